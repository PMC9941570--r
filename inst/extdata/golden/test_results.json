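{"modularity":{"settings":{"measure":"modularity","scheme":"groups","ages":[1,2,3,4,5,6,7,8,9],"Q":50,"seed":424242,"unit":"visit","length_rule":"weight","kernel":"gaussian"},"bandwidths":{"mean":0.949355818226418,"age":0.949355818226418,"age_by_group":[1.32819540765379,1.20603238924529,1.28494805942804,1.21517004325335],"elc":null},"discarded":0,"results":[{"age":1,"T_obs":0.0820954921862514,"p":0.74,"n_perm_used":50,"perm_quantiles":{"50%":0.147201959078714,"90%":0.319770644868921,"95%":0.374935698285446,"99%":0.467401663198768}},{"age":2,"T_obs":0.0538483973887818,"p":0.84,"n_perm_used":50,"perm_quantiles":{"50%":0.111969132213771,"90%":0.273014616129279,"95%":0.281071669434882,"99%":0.378813001084747}},{"age":3,"T_obs":0.0399190404949554,"p":0.9,"n_perm_used":50,"perm_quantiles":{"50%":0.0946889343325712,"90%":0.243580782557042,"95%":0.253473851773274,"99%":0.272639283417989}},{"age":4,"T_obs":0.0310723939738303,"p":0.88,"n_perm_used":50,"perm_quantiles":{"50%":0.0879450118157461,"90%":0.196876437768231,"95%":0.205571296070794,"99%":0.216043561064465}},{"age":5,"T_obs":0.0162212691275164,"p":0.96,"n_perm_used":50,"perm_quantiles":{"50%":0.0752584294166707,"90%":0.16621964754707,"95%":0.183927657600083,"99%":0.190304733610288}},{"age":6,"T_obs":0.0104891209274182,"p":0.96,"n_perm_used":50,"perm_quantiles":{"50%":0.0526796673256378,"90%":0.133309319811799,"95%":0.144921319705593,"99%":0.158526696695046}},{"age":7,"T_obs":0.0068408309291992,"p":0.96,"n_perm_used":50,"perm_quantiles":{"50%":0.0418642601140139,"90%":0.0852652000220317,"95%":0.090381018043075,"99%":0.0959187763695964}},{"age":8,"T_obs":0.00965964367935668,"p":0.86,"n_perm_used":50,"perm_quantiles":{"50%":0.0244737714255124,"90%":0.0545152259165554,"95%":0.061459521183623,"99%":0.0660220634449902}},{"age":9,"T_obs":0.000763430798997484,"p":1,"n_perm_used":50,"perm_quantiles":{"50%":0.00917526172080055,"90%":0.0207558119908428,"95%":0.0235400718532167,"99%":0.0327367431030965}}]},"global_efficiency":{"settings":{"measure":"global_efficiency","scheme":"groups","ages":[1,2,3,4,5,6,7,8,9],"Q":50,"seed":424242,"unit":"visit","length_rule":"weight","kernel":"gaussian"},"bandwidths":{"mean":0.949355818226418,"age":0.949355818226418,"age_by_group":[1.32819540765379,1.20603238924529,1.28494805942804,1.21517004325335],"elc":null},"discarded":0,"results":[{"age":1,"T_obs":0.397520341649421,"p":0.06,"n_perm_used":50,"perm_quantiles":{"50%":0.2062403508534,"90%":0.331066602801027,"95%":0.422240390165998,"99%":0.755498549222065}},{"age":2,"T_obs":0.346370496319165,"p":0.1,"n_perm_used":50,"perm_quantiles":{"50%":0.17166240725485,"90%":0.318510201330598,"95%":0.369558919591289,"99%":0.547719287162749}},{"age":3,"T_obs":0.332196052128618,"p":0.06,"n_perm_used":50,"perm_quantiles":{"50%":0.147714955152912,"90%":0.27942933603932,"95%":0.333172345178693,"99%":0.478939890238398}},{"age":4,"T_obs":0.30743178738831,"p":0.06,"n_perm_used":50,"perm_quantiles":{"50%":0.137559181755465,"90%":0.262043925496438,"95%":0.308920835863117,"99%":0.410165664914235}},{"age":5,"T_obs":0.284518648701323,"p":0.02,"n_perm_used":50,"perm_quantiles":{"50%":0.126761422473132,"90%":0.234407319293434,"95%":0.258298046218386,"99%":0.311384358039411}},{"age":6,"T_obs":0.231683889573447,"p":0.02,"n_perm_used":50,"perm_quantiles":{"50%":0.10749473703109,"90%":0.177503429229174,"95%":0.200392795985116,"99%":0.229178835591284}},{"age":7,"T_obs":0.139829530671673,"p":0.06,"n_perm_used":50,"perm_quantiles":{"50%":0.080556321559483,"90%":0.131943672581209,"95%":0.141986172954521,"99%":0.170158492089759}},{"age":8,"T_obs":0.0536709620635576,"p":0.44,"n_perm_used":50,"perm_quantiles":{"50%":0.040010820812658,"90%":0.0858685471192871,"95%":0.0932966533951186,"99%":0.103274170460166}},{"age":9,"T_obs":0.00727666745836556,"p":0.82,"n_perm_used":50,"perm_quantiles":{"50%":0.0156636091253916,"90%":0.0294291123290968,"95%":0.034050441168832,"99%":0.0360325155266328}}]}}
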