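strain_id,dataset,mu,mu_sd,q_glc,q_glc_sd,q_ac,q_ac_sd
ale_01,ale,1.13769278353227,0.0227538556706455,8.55110849751643,0.171022169950329,4.04782508997867,0.0809565017995733
ale_02,ale,0.995514866936676,0.0199102973387335,8.81942601873431,0.176388520374686,4.92862764062887,0.0985725528125774
ale_03,ale,1.07038008372299,0.0214076016744598,9.53908349032571,0.190781669806514,6.01176430031107,0.120235286006221
ale_04,ale,1.10496649315827,0.0220993298631654,11.0264929245683,0.220529858491366,6.86341279530657,0.137268255906131
ale_05,ale,1.01618029939753,0.0203236059879506,11.3868788135854,0.227737576271709,8.26103879551952,0.16522077591039
ale_06,ale,1.01400819079864,0.0202801638159728,11.7378072040712,0.234756144081423,9.13865237725081,0.182773047545016
ale_07,ale,1.09764149434319,0.0219528298868638,12.8414087271728,0.256828174543456,10.4226544111724,0.208453088223448
ale_08,ale,1.03324383278662,0.0206648766557324,13.9303915181749,0.278607830363499,11.5607029128882,0.231214058257763
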