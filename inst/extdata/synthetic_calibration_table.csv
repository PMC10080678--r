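"compound_id","a","b","c","A_max","mw_class"
"ERY",4.34911509673111e-05,0.89826299471315,0,1000,"C4"
"THR",9.17387010995299e-05,1.35928004502784,0,1000,"C4"
"ERO",9.08550716470927e-05,0.802522896556184,0,1000,"C4"
"THO",6.94718013238162e-05,1.91701290290803,0,1000,"C4"
"II_C5",1.55607643420808e-05,1.44367106584832,0,1000,"C5"
"II_C6a",2.58901077276096e-05,0.808961862348951,0,1000,"C6"
"II_C6b",4.45693346392363e-05,1.53053426998667,0,1000,"C6"
"II_C6c",5.47929317876697e-05,1.65476212999783,0,1000,"C6"
"II_C7a",9.92715485347435e-05,1.57642776239663,0,1000,"C7"
"II_C7b",7.99700699187815e-05,1.07005276915152,0,1000,"C7"
"III_C7",2.90928269154392e-05,1.90205784665886,0,1000,"C7"
"III_C8a",2.12999586365186e-05,1.47751064912882,0,1000,"C8"
"III_C8b",4.47502683289349e-05,0.900831003091298,0,1000,"C8"
"III_C8c",4.44149161363021e-05,0.520085499738343,0,1000,"C8"
"III_C9a",4.06314097018912e-05,1.8045362685807,0,1000,"C9"
"III_C9b",6.3960924288258e-05,1.22312017320655,0,1000,"C9"
"IV_C5",2.6759584126994e-05,1.24031196057331,0,1000,"C5"
"IV_C6a",7.01620064373128e-05,1.74105997791048,0,1000,"C6"
"IV_C6b",1.9714926329907e-05,1.69135979108978,0,1000,"C6"
"IV_C6c",4.70146986679174e-05,1.58556641906034,0,1000,"C6"
"IV_C7a",6.82354174437933e-05,1.73141944117378,0,1000,"C7"
"IV_C7b",5.97732680477202e-05,1.67439914343413,0,1000,"C7"
"V_C5",8.10420608520508e-05,1.29457937029656,0,1000,"C5"
"V_C6a",5.29507058532909e-05,0.53499680350069,0,1000,"C6"
"V_C6b",7.23458400834352e-05,1.5984706080053,0,1000,"C6"
"V_C6c",8.7508852914907e-05,1.2164294332033,0,1000,"C6"
"V_C7a",3.2031754932832e-05,1.15714566083625,0,1000,"C7"
"V_C7b",1.89519544155337e-05,0.606018570717424,0,1000,"C7"
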