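# Shared constants (this file must sort before conventions.R and taxonomy.R,
# which build tables from these at load time).

OBSERVABLE_GROUPS <- c(1L, 5L, 7L, 8L, 9L, 13L, 16L)

# tolerance band used to classify H* > 1: Paule-Mandel roots satisfy H* = 1
# only up to the root-finder's accuracy, and the taxonomy is designed so the
# strict/non-strict choice at exactly 1 carries no meaning.
HSTAR_ONE_TOL <- 1e-8

CONVENTIONS <- c("never", "always", "constrain", "hybrid1", "hybrid2",
                 "hybrid3")

ALL_LABELS <- c("Mod(t)", "RE(Z)", "RE(t)", "CE(Z)", "CE(t)")
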