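# Shared fixtures built in code.

# mean per-strain peak specific growth rate from a generated curve set
strain_peak_rates <- function(curves, window = 5, min_od = 0, method = "specific") {
  est <- vapply(split(curves, interaction(curves$strain, curves$replicate, drop = TRUE)),
                function(d) estimate_growth_constant(d$time_h, d$od, method,
                                                     window = window, min_od = min_od)$rate,
                numeric(1))
  tapply(est, sub("\\..*$", "", names(est)), mean)
}

# a tiny uniform codon-usage table (all sense codons equally used)
uniform_usage <- function() {
  codons <- as.vector(outer(as.vector(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                            paste0)), c("T", "C", "A", "G"), paste0))
  data.frame(codon = codons, count = 1)
}
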