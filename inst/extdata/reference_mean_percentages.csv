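scheme,group,parameter,a_pct,c_pct,e_pct
network,sensorimotor,intercept,33,11,56
network,sensorimotor,slope,16,12,72
network,social,intercept,34,12,54
network,social,slope,9,11,80
network,affective,intercept,30,12,58
network,affective,slope,23,7,70
roi,primary_motor,intercept,18,30,52
roi,primary_motor,slope,27,0,73
roi,somatosensory,intercept,35,13,52
roi,somatosensory,slope,17,11,62
roi,dlpfc,intercept,26,5,69
roi,dlpfc,slope,20,7,83
roi,cerebellum,intercept,59,0,41
roi,cerebellum,slope,2,28,70
roi,mpfc,intercept,33,0,67
roi,mpfc,slope,22,0,78
roi,tpj,intercept,25,17,58
roi,tpj,slope,1,16,84
roi,sts,intercept,30,17,53
roi,sts,slope,0,20,80
roi,precuneus,intercept,55,10,35
roi,precuneus,slope,29,0,71
roi,hippocampus,intercept,30,22,48
roi,hippocampus,slope,20,17,63
roi,amygdala,intercept,40,5,55
roi,amygdala,slope,24,0,76
roi,accumbens,intercept,20,10,70
roi,accumbens,slope,26,0,74
dimension,CT,intercept,14,15,71
dimension,CT,slope,15,6,79
dimension,SA,intercept,38,14,48
dimension,SA,slope,14,11,75
dimension,VO,intercept,37,9,54
dimension,VO,slope,17,13,70
network_dimension,sensorimotor:CT,intercept,17,12,71
network_dimension,sensorimotor:CT,slope,28,0,82
network_dimension,sensorimotor:SA,intercept,32,14,54
network_dimension,sensorimotor:SA,slope,17,14,69
network_dimension,sensorimotor:VO,intercept,59,0,41
network_dimension,sensorimotor:VO,slope,2,28,70
network_dimension,social:CT,intercept,8,20,72
network_dimension,social:CT,slope,7,10,83
network_dimension,social:SA,intercept,53,14,33
network_dimension,social:SA,slope,1,19,80
network_dimension,social:VO,intercept,NA,NA,NA
network_dimension,social:VO,slope,NA,NA,NA
network_dimension,affective:CT,intercept,NA,NA,NA
network_dimension,affective:CT,slope,NA,NA,NA
network_dimension,affective:SA,intercept,NA,NA,NA
network_dimension,affective:SA,slope,NA,NA,NA
network_dimension,affective:VO,intercept,30,12,58
network_dimension,affective:VO,slope,23,7,70
hemisphere,right,intercept,35,18,47
hemisphere,right,slope,17,20,63
hemisphere,left,intercept,32,20,48
hemisphere,left,slope,25,20,55
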