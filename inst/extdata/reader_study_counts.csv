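dataset,rater,region,grade,count,pct_printed,total
internal,orthopedist,NONE,0,198,49.50,400
internal,orthopedist,LEFZ,1,0,0.00,400
internal,orthopedist,LEFZ,2,1,0.25,400
internal,orthopedist,LEFZ,3,0,0.00,400
internal,orthopedist,LFZ,1,10,2.50,400
internal,orthopedist,LSAZ,1,17,4.25,400
internal,orthopedist,LSAZ,2,3,0.75,400
internal,orthopedist,LSAZ,3,0,0.00,400
internal,orthopedist,CCZ,1,64,16.00,400
internal,orthopedist,CCZ,2,61,15.25,400
internal,orthopedist,CCZ,3,6,1.50,400
internal,orthopedist,RSAZ,1,16,4.00,400
internal,orthopedist,RSAZ,2,2,0.50,400
internal,orthopedist,RSAZ,3,0,0.00,400
internal,orthopedist,RFZ,1,14,3.50,400
internal,orthopedist,REFZ,1,1,0.25,400
internal,orthopedist,REFZ,2,7,1.75,400
internal,orthopedist,REFZ,3,0,0.00,400
internal,model,NONE,0,185,46.25,400
internal,model,LEFZ,1,1,0.25,400
internal,model,LEFZ,2,3,0.75,400
internal,model,LEFZ,3,0,0.00,400
internal,model,LFZ,1,15,3.75,400
internal,model,LSAZ,1,23,5.75,400
internal,model,LSAZ,2,6,1.50,400
internal,model,LSAZ,3,0,0.00,400
internal,model,CCZ,1,54,13.50,400
internal,model,CCZ,2,64,16.00,400
internal,model,CCZ,3,8,2.00,400
internal,model,RSAZ,1,15,3.75,400
internal,model,RSAZ,2,2,0.50,400
internal,model,RSAZ,3,0,0.00,400
internal,model,RFZ,1,15,3.75,400
internal,model,REFZ,1,1,0.25,400
internal,model,REFZ,2,8,2.00,400
internal,model,REFZ,3,0,0.00,400
external,orthopedist,NONE,0,555,37.00,1500
external,orthopedist,LEFZ,1,5,0.33,1500
external,orthopedist,LEFZ,2,12,0.80,1500
external,orthopedist,LEFZ,3,0,0.00,1500
external,orthopedist,LFZ,1,114,7.60,1500
external,orthopedist,LSAZ,1,82,5.47,1500
external,orthopedist,LSAZ,2,14,0.93,1500
external,orthopedist,LSAZ,3,0,0.00,1500
external,orthopedist,CCZ,1,240,16.00,1500
external,orthopedist,CCZ,2,290,19.33,1500
external,orthopedist,CCZ,3,23,1.53,1500
external,orthopedist,RSAZ,1,45,3.00,1500
external,orthopedist,RSAZ,2,22,1.47,1500
external,orthopedist,RSAZ,3,0,0.00,1500
external,orthopedist,RFZ,1,80,5.33,1500
external,orthopedist,REFZ,1,4,0.27,1500
external,orthopedist,REFZ,2,13,0.87,1500
external,orthopedist,REFZ,3,1,0.07,1500
external,model,NONE,0,493,32.87,1500
external,model,LEFZ,1,4,0.27,1500
external,model,LEFZ,2,13,0.87,1500
external,model,LEFZ,3,0,0.00,1500
external,model,LFZ,1,137,9.13,1500
external,model,LSAZ,1,95,6.33,1500
external,model,LSAZ,2,15,1.00,1500
external,model,LSAZ,3,0,0.00,1500
external,model,CCZ,1,202,13.47,1500
external,model,CCZ,2,319,21.27,1500
external,model,CCZ,3,36,2.40,1500
external,model,RSAZ,1,56,3.73,1500
external,model,RSAZ,2,26,1.73,1500
external,model,RSAZ,3,1,0.07,1500
external,model,RFZ,1,81,5.40,1500
external,model,REFZ,1,5,0.33,1500
external,model,REFZ,2,16,1.07,1500
external,model,REFZ,3,1,0.07,1500
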