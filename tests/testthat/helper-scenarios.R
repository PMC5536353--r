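# Shared fixtures built in code.

# A small circular "repeat" for exhaustive coordinate checks.
tiny_cs <- function() rdna_coords(length = 200L, origin = 61L)

# The published repeat geometry.
bk_cs <- function() rdna_coords()

# A lone point source scenario on the full repeat: factor "src" at `center`,
# uniform input, shared sequence bias.
point_scenario <- function(center, footprint = 50, seed = 11L,
                           bias_range = 3) {
  cs <- rdna_coords()
  rdna_scenario(
    profiles = list(src = point_source_profile(cs$length, center,
                                               footprint = footprint),
                    input = rep(1, cs$length)),
    cs = cs, tss = 14815L, spacer_tss = 12708L,
    bias_range = bias_range, seed = seed)
}

# Noiseless exponential enrichment profile with the TSS at `tss`.
decay_track <- function(A = 8, Lc = 1298.3, B = 0.2, tss = 100L,
                        n = 7000L) {
  v <- rep(B, tss + n)
  d <- 0:(n - 1L)
  v[tss + d] <- A * exp(-d / Lc) + B
  as_enrichment_track(v)
}
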