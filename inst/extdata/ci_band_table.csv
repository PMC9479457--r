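id,age,brand,b_electrode,b_cf,moderate_electrode,moderate_cf,large_electrode,large_cf
CI1,53,Cochlear,11,1808,8,2927,2,6418
CI2,69,Cochlear,12,1683,8,2871,2,6485
CI3,69,MED-EL,7,1632,10,3064,12,7352
CI4,43,Cochlear,11,1741,7,3092,2,6828
CI5,24,Cochlear,12,1683,8,2871,2,6485
CI6,57,Cochlear,12,1683,8,2871,2,6485
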