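# Canonical tumor-bed component order. Ties in the increment-rounding repair
# are broken in this order, and all composition data frames carry these
# columns.
COMPONENTS <- c("viable_pct", "necrosis_pct", "inflammatory_pct", "fibrotic_pct")
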