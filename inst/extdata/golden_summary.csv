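"strain","DO_percent","depleted","acetate","lactate","formate","ethanol","succinate","t_dep","X","digest"
"WT","0",TRUE,"1.03237881572","0.174554754665","3.04807844594","1.74218392652","0.208124518566","13.2261660755","0.494880409836","078c91c530cef47b6c97c6504f7208a4"
"WT","1",TRUE,"1.03909523857","0.179714664069","3.04049309852","1.64758503888","0.194660493749","12.2310920481","0.556001568137","078c91c530cef47b6c97c6504f7208a4"
"WT","3",TRUE,"1.11431774834","0.420638596774","3.0006472889","1.51633982757","0.180566283662","10.5873360459","0.754357693128","078c91c530cef47b6c97c6504f7208a4"
"WT","8",TRUE,"1.07392485011","1.21142365879","0.00228243538349","1.825974499e-05","0.0228814454707","11.2506333076","2.93077082679","078c91c530cef47b6c97c6504f7208a4"
"WT","40",TRUE,"1.34647915573","0.340770754907","0.000435460063684","2.17319034287e-05","0.0123849875135","6.54484399215","3.24953791698","078c91c530cef47b6c97c6504f7208a4"
"fnr","0",TRUE,"0.380217040746","3.81162829254","1.75033798344","1.52516420414","0.00725290901023","16.1803907556","0.59431996594","078c91c530cef47b6c97c6504f7208a4"
"fnr","1",TRUE,"0.508485463993","3.99997969707","1.56069883317","1.18035756355","0.00957747863635","13.751754631","0.795872150114","078c91c530cef47b6c97c6504f7208a4"
"fnr","3",TRUE,"0.781569745993","4.2292899526","1.21580789665","0.49935044654","0.0148260132033","11.3461933613","1.18472209704","078c91c530cef47b6c97c6504f7208a4"
"fnr","8",TRUE,"1.04995711594","1.19674059756","0.00171100592154","1.75124485279e-05","0.017441380892","11.0897852178","2.94318697507","078c91c530cef47b6c97c6504f7208a4"
"fnr","40",TRUE,"1.34640271868","0.340765599532","0.000435257917297","2.17319331973e-05","0.012379368056","6.54482709522","3.24956016623","078c91c530cef47b6c97c6504f7208a4"
"arcA","0",TRUE,"0.449345175655","1.79066040461","1.20026605198","2.24298435235","0.353432940922","14.5646220369","0.576953465564","078c91c530cef47b6c97c6504f7208a4"
"arcA","1",TRUE,"0.497773577875","1.5775503389","1.01721533071","2.14168234561","0.293504754711","11.2007455155","0.832593161666","078c91c530cef47b6c97c6504f7208a4"
"arcA","3",TRUE,"0.55831717814","1.86110351033","0.487129313769","1.59353239604","0.19493577969","8.42680155015","1.3760243395","078c91c530cef47b6c97c6504f7208a4"
"arcA","8",TRUE,"0.990917058328","1.10768619931","0.0306157480577","0.313683409538","0.0139854359338","6.07513639931","2.74683227608","078c91c530cef47b6c97c6504f7208a4"
"arcA","40",TRUE,"1.45570555321","0.259505456016","0.000283051718604","2.68099120547e-05","0.0109409752186","6.03649739657","3.23546718794","078c91c530cef47b6c97c6504f7208a4"
"pfl","0",TRUE,"0.0612488528206","7.29044538813","0","0.336597304548","0.405239327748","19.3827481963","0.623140467288","078c91c530cef47b6c97c6504f7208a4"
"pfl","1",TRUE,"0.155317722902","7.0921747536","0","0.276258152058","0.317240023595","18.4169060022","0.729180632574","078c91c530cef47b6c97c6504f7208a4"
"pfl","3",TRUE,"0.423164609057","6.55404009999","0","0.0326709082509","0.149324473973","16.2402280287","1.03720502293","078c91c530cef47b6c97c6504f7208a4"
"pfl","8",TRUE,"1.07345560183","1.21149958248","0","1.77771866266e-05","0.0228655021278","11.2554604605","2.93156725439","078c91c530cef47b6c97c6504f7208a4"
"pfl","40",TRUE,"1.34634254809","0.340838543773","0","2.1729104492e-05","0.0123851906602","6.54541000079","3.249654197","078c91c530cef47b6c97c6504f7208a4"
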