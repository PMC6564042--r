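# Shared fixtures, built in code.

default_model <- function(...) ssme_model(...)

# a random but biologically sane parameterization; fermentation kept the
# proteome-cheaper ATP source so the overflow structure exists
random_model <- function() {
  k_fer <- runif(1, 15, 30)
  a_res <- runif(1, 20, 30)
  a_fer <- runif(1, 8, 15)
  # eps_fer * a_fer > eps_res * a_res  =>  k_res < k_fer * a_fer / a_res
  k_res <- runif(1, 0.3, 0.8) * k_fer * a_fer / a_res
  ssme_model(k_eff_res = k_res, k_eff_fer = k_fer,
             k_eff_bms = runif(1, 3, 10),
             UPF = runif(1, 0.2, 0.5), GAM = runif(1, 20, 60),
             NGAM = runif(1, 0, 4), a_res = a_res, a_fer = a_fer)
}

# hinge data generator for acetate-line tests
hinge_data <- function(threshold, slope, n = 20, mu_max = 1.2, sigma = 0) {
  mu <- seq(0.1, mu_max, length.out = n)
  q_ac <- pmax(0, slope * (mu - threshold))
  if (sigma > 0) q_ac <- pmax(0, q_ac + rnorm(n, 0, sigma))
  tibble::tibble(mu = mu, q_ac = q_ac)
}
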