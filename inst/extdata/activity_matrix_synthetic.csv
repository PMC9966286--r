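sample,TPC,TFC,DPPH,ABTS,TYR,AGLU,ELA
OP,24.25,23.98,87.56,172.36,59.53,221.59,372.25
HM,14.1,16.8,110.2,105.56,75.4,310.5,420.3
HE,11.6,9.8,190.3,130.4,140.6,340.2,400.8
HW,15.2,14.9,175.4,200.2,128.8,280.7,299.05
MM,11.8,12.1,160.8,210.9,118.3,360.9,320.6
ME,6.5,6.2,210.6,160.7,155.2,230.4,350.9
MW,7.2,7,232.3,245.8,170.7,380.6,430.1
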