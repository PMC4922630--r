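"sex","group","age","count"
"female","GroupA",2,3e+05
"female","GroupA",3,296422
"female","GroupA",4,292886
"female","GroupA",5,289392
"female","GroupA",6,285940
"female","GroupA",7,282529
"female","GroupA",8,279159
"female","GroupA",9,275829
"female","GroupA",10,272539
"female","GroupA",11,269288
"female","GroupA",12,266076
"female","GroupA",13,262902
"female","GroupA",14,259766
"female","GroupA",15,256668
"female","GroupA",16,253606
"female","GroupA",17,250581
"female","GroupA",18,247592
"female","GroupA",19,244639
"female","GroupA",20,241721
"female","GroupA",21,238837
"female","GroupA",22,235988
"female","GroupA",23,233173
"female","GroupA",24,230392
"female","GroupA",25,227644
"female","GroupA",26,224928
"female","GroupA",27,222245
"female","GroupA",28,219594
"female","GroupA",29,216975
"female","GroupA",30,214387
"female","GroupA",31,211830
"female","GroupA",32,209303
"female","GroupA",33,206806
"female","GroupA",34,204339
"female","GroupA",35,201902
"female","GroupA",36,199494
"female","GroupA",37,197114
"female","GroupA",38,194763
"female","GroupA",39,192440
"female","GroupA",40,190144
"female","GroupA",41,187876
"female","GroupA",42,185635
"female","GroupA",43,183421
"female","GroupA",44,181233
"female","GroupA",45,179071
"female","GroupA",46,176935
"female","GroupA",47,174824
"female","GroupA",48,172739
"female","GroupA",49,170679
"female","GroupA",50,168643
"female","GroupA",51,166631
"female","GroupA",52,164643
"female","GroupA",53,162680
"female","GroupA",54,160739
"female","GroupA",55,158822
"female","GroupA",56,156927
"female","GroupA",57,155055
"female","GroupA",58,153206
"female","GroupA",59,151378
"female","GroupA",60,149573
"female","GroupA",61,147789
"female","GroupA",62,146026
"female","GroupA",63,144284
"female","GroupA",64,142563
"female","GroupA",65,140862
"female","GroupA",66,139182
"female","GroupA",67,137522
"female","GroupA",68,135881
"female","GroupA",69,134261
"female","GroupA",70,132659
"female","GroupA",71,131077
"female","GroupA",72,129513
"female","GroupA",73,127968
"female","GroupA",74,126442
"female","GroupA",75,124934
"female","GroupA",76,123443
"female","GroupA",77,121971
"female","GroupA",78,120516
"female","GroupA",79,119078
"female","GroupA",80,117658
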