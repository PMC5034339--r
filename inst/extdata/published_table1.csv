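gleason,classifier,level,n,recurrence_pct
5-6,anisotropy,low,19,5.2
5-6,anisotropy,high,48,2.1
3+4,anisotropy,low,26,26.9
3+4,anisotropy,high,63,6.3
4+3,anisotropy,low,8,62.5
4+3,anisotropy,high,6,16.7
8-10,anisotropy,low,16,81.25
8-10,anisotropy,high,6,16.7
5-6,capra_s,0-2,65,1.5
5-6,capra_s,3-5,2,50
3+4,capra_s,0-2,63,9.5
3+4,capra_s,3-5,24,12.5
3+4,capra_s,6-11,2,100
4+3,capra_s,0-2,5,60
4+3,capra_s,3-5,5,40
4+3,capra_s,6-11,4,25
8-10,capra_s,3-5,14,57.1
8-10,capra_s,6-11,8,75
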