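patient_id,structure,mda,dose_ref,dose_est,dose_diff
Pt1,total,5.3,15.1,11.6,3.5
Pt2,total,7.9,15.1,13.1,2.0
Pt3,total,4.5,9.9,9.2,0.7
Pt4,total,4.9,7.9,8.1,-0.2
Pt5,total,3.8,10.3,10.6,-0.3
Pt6,total,5.5,14.5,8.7,5.7
Pt7,total,5.7,11.6,10.3,1.3
Pt8,total,4.5,10.7,9.2,1.5
Pt9,total,3.4,14.6,9.0,5.5
Pt10,total,2.9,18.5,17.2,1.3
Pt11,total,1.6,13.7,13.3,0.4
Pt12,total,1.2,9.8,12.4,-2.6
Pt13,total,6.5,13.6,14.2,-0.6
Pt14,total,4.7,6.0,10.9,-5.0
Pt1,ig,7.4,16.8,9.4,7.4
Pt2,ig,6.9,17.8,16.1,1.7
Pt3,ig,4.7,8.6,10.1,-1.5
Pt4,ig,3.9,8.3,7.5,0.8
Pt5,ig,5.5,12.1,8.0,4.0
Pt6,ig,7.0,22.9,19.5,3.4
Pt7,ig,6.0,10.9,12.1,-1.3
Pt8,ig,5.4,10.8,8.9,1.9
Pt9,ig,4.2,19.0,19.7,-0.7
Pt10,ig,3.3,15.4,18.2,-2.8
Pt11,ig,1.6,18.6,8.4,10.3
Pt12,ig,1.3,8.1,7.7,0.4
Pt13,ig,8.8,15.4,15.2,0.2
Pt14,ig,5.3,5.2,6.2,-1.0
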