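# IUPAC nucleotide code expansions. '-' expands to the empty set so that gap
# columns never "overlap" anything under the set-overlap distance policy.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = character(0)
)

.ALPHABET <- names(.IUPAC)
.UNAMBIGUOUS <- c("A", "C", "G", "T", "-")

# reverse lookup: sorted base set -> symbol
.IUPAC_REV <- local({
  keys <- vapply(.IUPAC, function(b) paste(sort(b), collapse = ""), "")
  out <- names(.IUPAC)
  names(out) <- keys
  out
})

.rdnadiv_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rdnadiv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
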