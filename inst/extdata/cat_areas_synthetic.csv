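subject_id,group,region,area_mm2
c1,control,striate,345.10
c2,control,striate,332.64
c3,control,striate,340.64
t1,treated,striate,198.20
t2,treated,striate,210.11
t3,treated,striate,204.77
c1,control,extrastriate,515.40
c2,control,extrastriate,503.95
c3,control,extrastriate,512.90
t1,treated,extrastriate,327.85
t2,treated,extrastriate,339.60
t3,treated,extrastriate,330.65
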