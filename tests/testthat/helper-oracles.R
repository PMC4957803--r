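# Independent brute-force oracles and small fixture builders.

# Benjamini-Hochberg step-up by direct enumeration of the formula.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Seed-site scan by per-pattern substring matching and containment
# resolution (structurally independent of the scanner's single-pass logic).
oracle_seed_scan <- function(utr, mir_seq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  utr <- chartr("tT", "uU", toupper(utr))
  core <- rc(substr(mir_seq, 2, 7))          # matches miRNA nt 2-7
  m8 <- comp[[substr(mir_seq, 8, 8)]]
  pats <- list("8mer" = paste0(m8, core, "A"),
               "7mer-m8" = paste0(m8, core),
               "7mer-A1" = paste0(core, "A"),
               "6mer" = core)
  n <- nchar(utr)
  find_all <- function(pat) {
    w <- nchar(pat)
    if (w > n) return(integer())
    starts <- seq_len(n - w + 1L)
    starts[vapply(starts, function(i) substr(utr, i, i + w - 1L) == pat,
                  FALSE)]
  }
  hits <- lapply(pats, find_all)
  # each core occurrence is one locus; assign the most specific type
  out <- lapply(hits$`6mer`, function(i) {
    has_m8 <- (i - 1L) %in% hits$`7mer-m8`
    has_a1 <- i %in% hits$`7mer-A1`
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    start0 <- (i - 1L) - has_m8
    end0 <- (i - 1L) + 6L + has_a1
    data.frame(start = start0, end = end0, site_type = type)
  })
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      site_type = character()))
  do.call(rbind, out)
}

# Exhaustive average-linkage (UPGMA) agglomeration over a distance matrix.
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(j, i) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Small annotated expression matrix with explicit per-group log2 means.
# group_means: probes x 4 matrix with columns WT_M0, WT_M1, KO_M0, KO_M1.
make_group_em <- function(group_means, sizes = c(WT_M0 = 3, WT_M1 = 3,
                                                 KO_M0 = 3, KO_M1 = 2),
                          noise_sd = 0, seed = NULL,
                          gene_symbols = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- rep(names(sizes), sizes)
  ids <- unlist(lapply(names(sizes), function(g)
    paste(g, seq_len(sizes[[g]]), sep = "_")), use.names = FALSE)
  E <- group_means[, groups, drop = FALSE] +
    matrix(rnorm(nrow(group_means) * length(groups), 0, noise_sd),
           nrow(group_means))
  dimnames(E) <- list(rownames(group_means), ids)
  sheet <- data.frame(sample_id = ids,
                      genotype = sub("_.*", "", groups),
                      condition = sub(".*_", "", groups))
  join_sample_sheet(expression_matrix(E, gene_symbols), sheet)
}

# Minimal contrast-like frame for unit tests of downstream rules.
fake_contrast <- function(probe_id, fc, gene_symbol = probe_id,
                          p_adj = rep(0.01, length(fc)),
                          p_raw = p_adj, label = "fake") {
  structure(data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                       fc = fc, p_raw = p_raw, p_adj = p_adj),
            class = c("contrast_result", "data.frame"), label = label)
}

# column indices of a GENOTYPE_CONDITION group in an annotated matrix
group_sizes_idx <- function(em, group) {
  parts <- strsplit(group, "_")[[1]]
  which(em$samples$genotype == parts[1] & em$samples$condition == parts[2])
}

random_utr <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

MIR155 <- mature_mirna("miR-155-5p", "UUAAUGCUAAUUGUGAUAGGGGU")
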