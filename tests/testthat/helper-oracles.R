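# Independent oracles and small fixture builders used across tests.

# brute-force AUC: all positive/negative pairs, ties worth 1/2
auc_brute <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# a hand-built fold assignment (bypasses the RNG)
manual_folds <- function(fold_of) {
  structure(list(n = length(fold_of), J = max(fold_of),
                 fold_of = as.integer(fold_of), seed = 0L,
                 stratified = FALSE),
            class = "fold_assignment")
}

# random rigid-body rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, byrow = TRUE)
  Rz(th[1]) %*% Rx(th[2]) %*% Rz(th[3])
}

# write a generated complex to a temp PDB and parse it back
complex_from_gen <- function(planted, seed = 1, ...) {
  g <- gen_complex(planted = planted, seed = seed, ...)
  tf <- tempfile(fileext = ".pdb")
  writeLines(g$pdb, tf)
  list(cx = parse_complex(tf), gen = g, path = tf)
}

# a synthetic PLIP-style XML report with the given per-category counts
synthetic_plip_xml <- function(counts) {
  item <- function(tag, i) {
    sprintf("<%s id=\"%d\"><restype>ASP</restype><resnr>%d</resnr><reschain>A</reschain></%s>",
            tag, i, i, tag)
  }
  sections <- vapply(names(counts), function(tag) {
    plural <- paste0(tag, "s")
    inner <- paste(vapply(seq_len(counts[[tag]]), item, "", tag = tag),
                   collapse = "")
    sprintf("<%s>%s</%s>", plural, inner, plural)
  }, "")
  paste0("<report><bindingsite><interactions>",
         paste(sections, collapse = ""),
         "</interactions></bindingsite></report>")
}
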