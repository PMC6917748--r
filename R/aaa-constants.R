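# Shared column-order constants.

# The six unique elements of a symmetric displacement tensor, in PDB ANISOU
# order (diagonal first, then off-diagonals).
U_COLS <- c("u11", "u22", "u33", "u12", "u13", "u23")

# Fields that uniquely identify an atom within one coordinate file.
KEY_COLS <- c("chain", "resno", "insert", "resid", "elety", "alt")

# 12-D clustering feature order: odd-state tensor elements, then even-state.
FEATURE_COLS <- c(paste0(U_COLS, "_odd"), paste0(U_COLS, "_even"))

`%||%` <- function(a, b) if (is.null(a)) b else a
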