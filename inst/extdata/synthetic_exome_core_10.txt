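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
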