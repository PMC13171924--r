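# Shared fixture builders: everything is generated in code at test time.

tiny_counts_tsv <- function(path, cells = rbind(c(1, 0), c(2, 3)),
                            taxa = c("t1", "t2"), samples = c("s1", "s2")) {
  lines <- c(paste(c("taxon_id", samples), collapse = "\t"),
             vapply(seq_along(taxa), function(i) {
               paste(c(taxa[i], cells[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  path
}

tiny_metadata <- function(n_rep = 2, cultivar = "Nadine",
                          compartments = c("flesh", "peel")) {
  md <- expand.grid(generation = c("seed", "daughter", "granddaughter"),
                    compartment = compartments, replicate = seq_len(n_rep),
                    stringsAsFactors = FALSE)
  md$cultivar <- cultivar
  md$field <- ifelse(md$generation == "seed", "", "F1")
  md$sample_id <- sprintf("s%02d", seq_len(nrow(md)))
  md[c("sample_id", "generation", "compartment", "cultivar", "field", "replicate")]
}

# Dataset whose presence structure is fully known: taxa are assigned to
# explicit (generation, compartment) membership.
tiny_dataset <- function(n_rep = 2) {
  md <- tiny_metadata(n_rep = n_rep)
  taxa <- paste0("asv", 1:8)
  counts <- matrix(0L, length(taxa), nrow(md),
                   dimnames = list(taxa, md$sample_id))
  present <- list(
    asv1 = c("seed", "daughter", "granddaughter"),  # fully vertical
    asv2 = c("seed", "daughter"),                   # lost at granddaughter
    asv3 = c("seed"),                               # never transferred
    asv4 = c("daughter", "granddaughter"),          # horizontal at daughter
    asv5 = c("granddaughter"),                      # horizontal at granddaughter
    asv6 = c("seed", "granddaughter"),              # seed taxon skipping daughter
    asv7 = c("seed", "daughter", "granddaughter"),
    asv8 = c("daughter")
  )
  for (tx in names(present)) {
    for (g in present[[tx]]) {
      cols <- md$sample_id[md$generation == g & md$compartment == "flesh"]
      counts[tx, cols] <- 5L
    }
  }
  validate_dataset(counts, md)
}

# Independent brute-force CSS oracle: literal sort / nearest-rank / sum.
css_oracle <- function(mat, q) {
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    nz <- sort(mat[mat[, j] > 0, j])
    qv <- nz[ceiling(q * length(nz))]
    s <- 0
    for (i in seq_len(nrow(mat))) {
      if (mat[i, j] > 0 && mat[i, j] <= qv) s <- s + mat[i, j]
    }
    out[j] <- s
  }
  out
}

# Independent one-way ANOVA (method-of-moments) oracle from explicit sums of
# squares.
mom_oracle <- function(values, labels) {
  g <- as.character(labels)
  lv <- unique(g)
  N <- length(values)
  a <- length(lv)
  grand <- sum(values) / N
  ssb <- 0; ssw <- 0; nsq <- 0
  for (l in lv) {
    v <- values[g == l]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
    nsq <- nsq + length(v)^2
  }
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  n0 <- (N - nsq / N) / (a - 1)
  vg <- max(0, (msb - msw) / n0)
  list(vg = vg, ve = msw, h2 = if (vg + msw == 0) 0 else vg / (vg + msw),
       interior = msb > msw)
}

# Brute-force one-way PERMANOVA oracle on a distance matrix: explicit
# within/between sums of squares over group assignments.
permanova_oracle_f <- function(dm, groups) {
  n <- nrow(dm)
  ss_total <- sum(dm[lower.tri(dm)]^2) / n
  lv <- unique(groups)
  ss_within <- 0
  for (l in lv) {
    idx <- which(groups == l)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (length(lv) - 1)) / (ss_within / (n - length(lv)))
}
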