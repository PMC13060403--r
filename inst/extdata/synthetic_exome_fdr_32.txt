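SYNGENE001
SYNGENE002
SYNGENE003
SYNGENE004
SYNGENE005
SYNGENE006
SYNGENE007
SYNGENE008
SYNGENE009
SYNGENE010
SYNGENE011
SYNGENE012
SYNGENE013
SYNGENE014
SYNGENE015
SYNGENE016
SYNGENE017
SYNGENE018
SYNGENE019
SYNGENE020
SYNGENE021
SYNGENE022
SYNGENE023
SYNGENE024
SYNGENE025
SYNGENE026
SYNGENE027
SYNGENE028
SYNGENE029
SYNGENE030
SYNGENE031
SYNGENE032
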