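# Default activation-pathway residue pairs (GPCRdb generic numbering).
# One pair per line; line order defines descriptor component order.
# TM5/TM6 packing, microswitches and G-protein coupling region
5x62 6x37
7x45 7x49
3x46 6x37
7x54 8x51
2x50 3x39
2x50 7x49
5x58 6x40
6x40 7x49
5x55 6x41
5x51 6x44
3x43 6x41
3x50 7x53
# PIF motif
3x40 6x44
3x40 5x50
5x50 6x44
# CWxP and the sodium pocket
6x44 7x45
6x47 7x45
6x48 7x45
6x48 7x50
3x39 7x45
2x50 7x45
2x50 7x46
3x39 7x49
# NPxxY and helix 8
7x49 7x53
7x53 8x50
2x43 7x53
3x46 7x53
3x43 7x49
3x43 7x53
# DRY / ionic lock and intracellular coupling interface
3x50 6x30
3x50 6x37
5x58 7x53
3x46 6x40
5x61 6x33
3x50 6x33
5x62 6x33
1x53 7x53
3x43 6x40
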