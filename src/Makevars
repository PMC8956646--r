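# keep pair-distance arithmetic bitwise-identical to base R (no FMA
# contraction), so histogram bin assignment at exact bin edges matches the
# R reference paths
PKG_CXXFLAGS = -ffp-contract=off
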