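mk_matrix <- function(rows, cols) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), cols)
  class(m) <- c("meth_matrix", class(m))
  m
}

# 12-row differential fixture covering both calling conditions, both failure
# modes, and the exact twofold boundary; columns are (B heart c1, B heart c2,
# A heart c1, A heart c2).
fixture_matrix <- function() {
  cols <- c("B|heart|1", "B|heart|2", "A|heart|1", "A|heart|2")
  mk_matrix(list(
    F01 = c(3.0, 3.0, 1.5, 0.0),   # hyper, condition i (3.0 >= 2*1.5)
    F02 = c(2.0, 2.0, 0.0, 0.0),   # hyper, condition ii
    F03 = c(2.9, 2.9, 1.2, 0.0),   # no call: fails i (<3) and ii (ref >= 1)
    F04 = c(3.0, 3.0, 1.6, 0.0),   # no call: 3.0 < 2*1.6, ref >= 1
    F05 = c(3.2, 3.2, 1.6, 0.0),   # hyper, condition i (exact 2x boundary)
    F06 = c(2.0, 2.0, 0.99, 0.0),  # hyper, condition ii (ref just under 1)
    F07 = c(2.0, 2.0, 1.0, 0.0),   # no call: ref not < 1
    F08 = c(1.9, 0.0, 0.0, 0.0),   # no call: test < 2
    F09 = c(0.0, 0.0, 0.0, 0.0),   # no call: empty row
    F10 = c(5.0, 5.0, 0.0, 0.0),   # hyper, condition i takes precedence
    F11 = c(0.0, 0.0, 3.5, 3.5),   # hypo in B (methylated in A only)
    F12 = c(4.0, 4.0, 4.0, 4.0)    # no call: equal in both strains
  ), cols)
}
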