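pdb_id,ligand,watsite_nn,watsite,mm_gbsa,experimental
1ZND,PE9,-24.4,-23.4,-33.9,-23.1
1ZNE,HE2,-27.6,-27.2,-39.0,-28.3
1ZNG,HE4,-33.1,-23.2,-27.2,-32.5
1ZNH,OC9,-36.2,-36.4,-23.2,-35.6
1ZNK,F09,-34.8,-36.4,-38.1,-38.8
1QY1,IBMP,-40.3,-36.8,-30.2,-38.5
1QY2,IPMP,-35.3,-41.1,-28.2,-33.9
1IO6,SBT,-35.3,-35.9,-38.4,-35.3
1I06,PT,-32.0,-39.4,-34.7,-34.3
1I06,IPT,-31.0,-35.9,-34.2,-32.6
1IO6,ET,-29.8,-29.5,-30.5,-29.2
1I06,MT,-26.5,-21.6,-28.9,-24.2
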