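compound_id,name,class,ic50_um,clogp
B1,Araguspongine C,B,6.60,4.7
B2,Xestospongin B,B,5.01,7.2
B3,Demethylated Xestospongin B,B,5.86,6.8
B4,7-(OH)-XeA,B,6.40,6.8
B5,Xestospongin A,B,2.53,8.1
B6,Araguspongine B,B,0.65,8.0
C1,BiPh(2;3';4;5';6)P5,C,0.42,-4.2
C2,BiPh(2;2'4;4';5;5')P6,C,0.19,-6.1
C3,"1,2,4-Dimer Biph(2;2';4;4';5;5')P6",C,0.38,-8.2
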