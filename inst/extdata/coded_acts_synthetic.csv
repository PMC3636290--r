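meeting_id,coder_id,act_index,theme
M1,A,1,clinical_judgment
M1,A,2,clinical_judgment
M1,A,3,clinical_judgment
M1,A,4,own_experience
M1,A,5,clinical_judgment
M1,A,6,contra_evidence
M1,A,7,clinical_judgment
M1,A,8,clinical_judgment
M1,A,9,clinical_judgment
M1,A,10,clinical_judgment
M1,A,11,procedural
M1,A,12,clinical_judgment
M1,A,13,clinical_judgment
M1,A,14,clinical_judgment
M1,A,15,uncertainty
M1,A,16,clinical_judgment
M1,A,17,contra_evidence
M1,A,18,clinical_judgment
M1,A,19,uncertainty
M1,A,20,clinical_judgment
M1,B,1,procedural
M1,B,2,clinical_judgment
M1,B,3,pro_evidence
M1,B,4,own_experience
M1,B,5,clinical_judgment
M1,B,6,contra_evidence
M1,B,7,other
M1,B,8,clinical_judgment
M1,B,9,clinical_judgment
M1,B,10,clinical_judgment
M1,B,11,procedural
M1,B,12,clinical_judgment
M1,B,13,clinical_judgment
M1,B,14,clinical_judgment
M1,B,15,uncertainty
M1,B,16,clinical_judgment
M1,B,17,contra_evidence
M1,B,18,clinical_judgment
M1,B,19,uncertainty
M1,B,20,clinical_judgment
M2,A,1,uncertainty
M2,A,2,uncertainty
M2,A,3,clinical_judgment
M2,A,4,uncertainty
M2,A,5,clinical_judgment
M2,A,6,clinical_judgment
M2,A,7,clinical_judgment
M2,A,8,uncertainty
M2,A,9,other
M2,A,10,uncertainty
M2,A,11,clinical_judgment
M2,A,12,uncertainty
M2,A,13,clinical_judgment
M2,A,14,clinical_judgment
M2,A,15,uncertainty
M2,A,16,pro_evidence
M2,A,17,other
M2,A,18,other
M2,A,19,clinical_judgment
M2,A,20,procedural
M2,A,21,clinical_judgment
M2,A,22,clinical_judgment
M2,B,1,uncertainty
M2,B,2,uncertainty
M2,B,3,clinical_judgment
M2,B,4,uncertainty
M2,B,5,clinical_judgment
M2,B,6,clinical_judgment
M2,B,7,uncertainty
M2,B,8,uncertainty
M2,B,9,other
M2,B,10,uncertainty
M2,B,11,clinical_judgment
M2,B,12,uncertainty
M2,B,13,clinical_judgment
M2,B,14,clinical_judgment
M2,B,15,uncertainty
M2,B,16,pro_evidence
M2,B,17,other
M2,B,18,other
M2,B,19,clinical_judgment
M2,B,20,procedural
M2,B,21,uncertainty
M2,B,22,clinical_judgment
M3,A,1,procedural
M3,A,2,procedural
M3,A,3,uncertainty
M3,A,4,other
M3,A,5,uncertainty
M3,A,6,other
M3,A,7,own_experience
M3,A,8,procedural
M3,A,9,own_experience
M3,A,10,uncertainty
M3,A,11,uncertainty
M3,A,12,clinical_judgment
M3,A,13,uncertainty
M3,A,14,clinical_judgment
M3,A,15,uncertainty
M3,A,16,clinical_judgment
M3,A,17,pro_evidence
M3,A,18,clinical_judgment
M3,A,19,contra_evidence
M3,A,20,clinical_judgment
M3,A,21,pro_evidence
M3,A,22,clinical_judgment
M3,A,23,clinical_judgment
M3,A,24,clinical_judgment
M3,A,25,own_experience
M3,A,26,clinical_judgment
M3,B,1,procedural
M3,B,2,procedural
M3,B,3,uncertainty
M3,B,4,other
M3,B,5,uncertainty
M3,B,6,other
M3,B,7,own_experience
M3,B,8,procedural
M3,B,9,own_experience
M3,B,10,uncertainty
M3,B,11,uncertainty
M3,B,12,clinical_judgment
M3,B,13,uncertainty
M3,B,14,clinical_judgment
M3,B,15,uncertainty
M3,B,16,clinical_judgment
M3,B,17,pro_evidence
M3,B,18,clinical_judgment
M3,B,19,contra_evidence
M3,B,20,clinical_judgment
M3,B,21,pro_evidence
M3,B,22,clinical_judgment
M3,B,23,other
M3,B,24,clinical_judgment
M3,B,25,own_experience
M3,B,26,clinical_judgment
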