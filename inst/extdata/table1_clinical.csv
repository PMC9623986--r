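patient_id,sample_id,sample_site,line_number,drug,non_target_therapy,response,pfs_months,event_observed,rank,bes,t_stage,n_stage,distant_metastases,ras_mutant
CC-1,CC-1,primary colorectal cancer,1,regorafenib,,progressive disease,3,1,160,-62.1,NA,NA,NA,TRUE
CC-2,CC-2,primary colorectal cancer,1,bevacizumab,FOLFOX,progressive disease,3,1,104,-0.9,3,2,TRUE,TRUE
CC-4,CC-4,primary colorectal cancer,1,panitumumab,FOLFIRI,progressive disease,2,1,139,-9.5,4,2,FALSE,FALSE
CC-5,CC-5,primary colorectal cancer,1,bevacizumab,FOLFIRI,progressive disease,5,1,81,-0.8,NA,2,TRUE,TRUE
CC-6,CC-6,primary colorectal cancer,1,cetuximab,FOLFIRI,progressive disease,3,1,90,-2.6,4,2,TRUE,FALSE
CC-18,CC-18,primary colorectal cancer,1,cetuximab,XELOX,progressive disease,8,1,137,-9.3,3,1,TRUE,FALSE
CC-34,CC-34,primary colorectal cancer,1,bevacizumab,FOLFOX,progressive disease,4,1,19,4.4,4,2,TRUE,TRUE
CC-35,CC-35,liver metastasis,1,bevacizumab,FOLFIRI,partial response,12,1,5,40.1,3,1,TRUE,FALSE
CC-41,CC-41,liver metastasis,1,bevacizumab,FOLFOX,stable disease,9,1,5,7.9,4,0,FALSE,FALSE
CC-44,CC-44,primary colorectal cancer,1,bevacizumab,FOLFOX,stable disease,11,1,22,3.5,3,0,TRUE,FALSE
CC-45,CC-45,peritoneal metastasis,1,bevacizumab,FOLFIRINOX,stable disease,20,1,1,35.1,4,1,TRUE,TRUE
CC-64,CC-64,brain metastasis,1,bevacizumab,FOLFIRI,progressive disease,5,1,6,24.3,3,0,TRUE,FALSE
CC-65,CC-65,primary colorectal cancer,1,bevacizumab,FOLFIRINOX,partial response,6,1,22,3.1,4,2,TRUE,TRUE
CC-72,CC-72,liver metastasis,1,aflibercept,FOLFIRI,progressive disease,3,1,166,-107.9,3,2,TRUE,TRUE
CC_91,CC_91,small intestine metastasis,1,bevacizumab,capecitabine,stable disease,13,1,6,9.0,3,1,TRUE,TRUE
CC-94,CC-94,adrenal gland metastasis,1,bevacizumab,FOLFIRI,partial response,5,1,27,6.6,3,1,TRUE,FALSE
CC-95,CC-95,liver metastasis,1,bevacizumab,FOLFOX,progressive disease,4,1,99,0.3,3,1,TRUE,FALSE
CC-105,CC-105,primary colorectal cancer,1,regorafenib,,progressive disease,3,1,113,-3.0,3,1,TRUE,FALSE
CC-107,CC-107,primary colorectal cancer,1,bevacizumab,FOLFOX,stable disease,4,1,22,1.7,3,2,TRUE,TRUE
CC-109,CC-109,peritoneal metastasis,1,bevacizumab,FOLFIRI,stable disease,8,1,11,5.7,4,0,TRUE,FALSE
CC-111,CC-111,peritoneal metastasis,1,bevacizumab,FOLFOX,progressive disease,2,1,165,-18.3,3,0,TRUE,TRUE
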