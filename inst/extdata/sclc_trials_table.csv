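trial_id,phase,experimental_arms,control_arm,primary_endpoint,n_patients,response_system,n_arms
KEYNOTE-604,III,Pembrolizumab + EP/EC,Placebo + EP/EC,PFS and OS,453,RECIST 1.1,2
IMpower133,III,Atezolizumab + EC,Placebo + EC,PFS and OS,403,RECIST 1.1,2
EA5161,II,Nivolumab + EP/EC,EP/EC,PFS,145,RECIST 1.1,2
CASPIAN,III,Durvalumab + EP/EC;Durvalumab + tremelimumab + EP/EC,EP/EC,OS,805,RECIST 1.1,3
Reck2012,II,phased-ipilimumab + paclitaxel + carboplatin;concurrent-ipilimumab + paclitaxel + carboplatin,Placebo + paclitaxel + carboplatin,irPFS,130,mWHO & irRC,3
Reck2016,III,Ipilimumab + EP/EC,Placebo + EP/EC,OS,954,mWHO,2
EORTC,II,Pembrolizumab + EP/EC,Placebo + EP/EC,PFS,119,NR,2
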