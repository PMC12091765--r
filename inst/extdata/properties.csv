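drug,BP,E,FP,MR,PSA,P,MV,MW
arbidol,591.8,91.5,311.7,121.9,80.0,48.3,347.30,477.40
chloroquine,460.6,72.1,232.3,97.4,28.2,38.6,287.90,319.90
hydroxychloroquine,516.7,83.0,266.3,99.0,48.4,39.2,285.40,335.90
lopinavir,924.2,140.8,512.7,179.2,120.0,71.0,540.50,628.80
remdesivir,,,,149.5,204.0,59.3,409.00,602.60
ritonavir,947.0,144.4,526.6,198.9,202.0,78.9,581.70,720.90
thalidomide,487.8,79.4,248.8,65.2,83.6,25.9,161.00,258.23
theaflavin,1003.9,153.5,336.5,137.3,218.0,54.4,301.00,564.50
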