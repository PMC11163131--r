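# Hand-entered heavy-atom connectivity used across tests.

# Naphazoline: naphthalene (a1..a10, fusion bond a5-a6), exocyclic methylene
# c1 on a1, 2-imidazoline ring i1-n2-c3-c4-n5 attached through i1.
naphazoline_edges <- function() {
  rbind(
    c("a1", "a2"), c("a2", "a3"), c("a3", "a4"), c("a4", "a5"),
    c("a5", "a6"), c("a6", "a1"), c("a5", "a7"), c("a7", "a8"),
    c("a8", "a9"), c("a9", "a10"), c("a10", "a6"),
    c("a1", "c1"), c("c1", "i1"),
    c("i1", "n2"), c("n2", "c3"), c("c3", "c4"), c("c4", "n5"), c("n5", "i1")
  )
}

# Foscarnet (phosphonoformate): P carries three exocyclic oxygens plus the
# carboxyl carbon, which carries two oxygens.
foscarnet_edges <- function() {
  rbind(
    c("P", "O1"), c("P", "O2"), c("P", "O3"), c("P", "C"),
    c("C", "O4"), c("C", "O5")
  )
}

star_edges <- function(k) cbind("hub", paste0("leaf", seq_len(k)))

cycle_edges <- function(n) {
  v <- paste0("v", seq_len(n))
  cbind(v, v[c(2:n, 1)])
}

# complete graph on labelled vertices
complete_edges <- function(n) {
  v <- paste0("v", seq_len(n))
  t(combn(v, 2))
}

# Independent oracle: topological indices summed edge by edge from an
# explicit edge list, using its own degree bookkeeping and formula table
# (no package code beyond the constructor under test is involved).
oracle_index <- function(pairs, index, frr_variant = "as_stated") {
  deg <- table(c(pairs[, 1], pairs[, 2]))
  total <- 0
  for (k in seq_len(nrow(pairs))) {
    d1 <- as.numeric(deg[[pairs[k, 1]]])
    d2 <- as.numeric(deg[[pairs[k, 2]]])
    hi <- max(d1, d2); lo <- min(d1, d2)
    total <- total + switch(index,
      M1  = d1 + d2,
      M2  = d1 * d2,
      mM2 = 1 / (d1 * d2),
      H   = 2 / (d1 + d2),
      F   = d1^2 + d2^2,
      HM  = (d1 + d2)^2,
      SD  = d1 / d2 + d2 / d1,
      FRR = if (frr_variant == "as_stated") 1 / (d1 * d2 + d1 + d2)
            else 1 / sqrt(2 * (d1 * d2 + d1 + d2)),
      SRR = (hi - lo + 1) / sqrt(hi * lo))
  }
  total
}

partition_as_counts <- function(part) {
  stats::setNames(part$count, paste(part$low, part$high, sep = "-"))
}
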