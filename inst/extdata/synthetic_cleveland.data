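50,1,4,130,280,1,0,150,1,1.5,2,1,7,1
50,1,4,170,180,1,2,150,1,1.5,3,1,7,1
70,0,4,130,220,0,2,150,1,1.5,2,0,7,1
70,1,4,110,280,0,2,150,1,1.5,1,?,7,1
50,1,4,150,220,0,0,150,1,1.5,2,0,7,1
50,0,4,110,280,0,0,150,1,1.5,1,1,7,1
50,0,3,150,180,0,0,150,0,0,2,0,3,0
50,0,3,130,180,0,0,150,1,1.5,1,0,3,0
50,1,4,130,180,1,0,150,0,1.5,1,2,7,1
50,0,4,110,280,1,0,150,1,0,1,0,7,0
50,0,4,130,280,0,2,150,1,0,2,0,?,1
50,1,3,170,245,0,2,150,1,1.5,2,0,3,1
50,1,3,130,280,1,0,150,0,1.5,1,1,3,0
50,0,1,110,220,0,0,150,0,1.5,2,0,7,0
50,0,2,150,220,0,2,90,0,1.5,1,1,7,0
50,1,3,150,280,0,0,150,1,1.5,1,0,7,1
50,1,2,130,220,0,0,150,0,1.5,1,1,3,1
50,0,3,110,220,0,0,150,1,1.5,2,0,3,0
50,1,2,110,245,0,2,150,0,1.5,1,0,7,1
70,1,3,110,280,0,0,150,0,0,3,0,3,0
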