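gene
EVGENE001
EVGENE002
EVGENE003
EVGENE004
EVGENE005
EVGENE006
EVGENE007
EVGENE008
EVGENE009
EVGENE010
EVGENE011
EVGENE012
EVGENE013
EVGENE014
EVGENE015
EVGENE016
EVGENE017
EVGENE018
EVGENE019
EVGENE020
EVGENE021
EVGENE022
EVGENE023
EVGENE024
EVGENE025
EVGENE026
EVGENE027
EVGENE028
EVGENE029
EVGENE030
EVGENE031
EVGENE032
EVGENE033
EVGENE034
EVGENE035
EVGENE036
EVGENE037
EVGENE038
EVGENE039
EVGENE040
EVGENE041
EVGENE042
EVGENE043
EVGENE044
EVGENE045
EVGENE046
EVGENE047
EVGENE048
EVGENE049
EVGENE050
EVGENE051
EVGENE052
EVGENE053
EVGENE054
EVGENE055
EVGENE056
EVGENE057
EVGENE058
EVGENE059
EVGENE060
EVGENE061
EVGENE062
EVGENE063
EVGENE064
EVGENE065
EVGENE066
EVGENE067
EVGENE068
EVGENE069
EVGENE070
EVGENE071
EVGENE072
EVGENE073
EVGENE074
EVGENE075
EVGENE076
EVGENE077
EVGENE078
EVGENE079
EVGENE080
EVGENE081
EVGENE082
EVGENE083
EVGENE084
EVGENE085
EVGENE086
EVGENE087
EVGENE088
EVGENE089
EVGENE090
EVGENE091
EVGENE092
EVGENE093
EVGENE094
EVGENE095
EVGENE096
EVGENE097
EVGENE098
EVGENE099
EVGENE100
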