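# Independent oracles used to cross-check the package's query machinery.
# They deliberately avoid the code paths they verify: the subgraph matcher
# below is a plain backtracking monomorphism search, the property-query
# oracle a direct row scan over the exported table, and the CAS oracle a
# from-scratch checksum recomputation.

# -- brute-force subgraph isomorphism (monomorphism) -----------------------
# Graphs are element + ring-membership labelled; a pattern atom maps to a
# target atom with the same element and ring flag, and every pattern bond
# must map onto an existing target bond (orders ignored, so Kekule
# alternation cannot cause spurious mismatches). Within the fixture grammar
# ring membership coincides with aromaticity, which is what the SMARTS
# route distinguishes.
oracle_graph <- function(smiles) {
  can <- molstash::smiles_canonical(smiles)
  stopifnot(!is.na(can))
  sdf <- molstash:::.smiles_to_sdfset(can)
  molstash:::.mol_graph(sdf[[1]])
}

oracle_subgraph_match <- function(pattern_graph, target_graph) {
  pg <- pattern_graph; tg <- target_graph
  np <- pg$n; nt <- tg$n
  if (np == 0L) return(TRUE)
  if (np > nt) return(FALSE)
  t_adj <- matrix(FALSE, nt, nt)
  if (nrow(tg$bonds)) {
    t_adj[tg$bonds[, 1:2]] <- TRUE
    t_adj[tg$bonds[, 2:1]] <- TRUE
  }
  p_nbr <- vector("list", np)
  if (nrow(pg$bonds)) {
    for (k in seq_len(nrow(pg$bonds))) {
      a <- pg$bonds[k, 1]; b <- pg$bonds[k, 2]
      p_nbr[[a]] <- c(p_nbr[[a]], b)
      p_nbr[[b]] <- c(p_nbr[[b]], a)
    }
  }
  p_deg <- lengths(p_nbr)
  t_deg <- rowSums(t_adj)
  label_ok <- outer(seq_len(np), seq_len(nt), Vectorize(function(i, j) {
    pg$atoms[i] == tg$atoms[j] && pg$in_ring[i] == tg$in_ring[j] &&
      p_deg[i] <= t_deg[j]
  }))
  assign <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)
  search <- function(i) {
    if (i > np) return(TRUE)
    for (j in which(label_ok[i, ] & !used)) {
      ok <- TRUE
      for (nb in p_nbr[[i]]) {
        if (!is.na(assign[nb]) && !t_adj[j, assign[nb]]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign[i] <<- j; used[j] <<- TRUE
      if (search(i + 1L)) return(TRUE)
      assign[i] <<- NA_integer_; used[j] <<- FALSE
    }
    FALSE
  }
  search(1L)
}

oracle_has_substructure <- function(target_smiles, query_smiles) {
  qg <- oracle_graph(query_smiles)
  vapply(target_smiles, function(s)
    oracle_subgraph_match(qg, oracle_graph(s)), logical(1),
    USE.NAMES = FALSE)
}

# -- brute-force property query -------------------------------------------
# Direct scan over the exported data.frame; returns the kept IDs.
oracle_property_query <- function(project, filters) {
  df <- as.data.frame(project)
  keep <- rep(TRUE, nrow(df))
  for (f in filters) {
    vals <- df[[f$column]]
    res <- logical(nrow(df))
    for (r in seq_len(nrow(df))) {
      v <- vals[r]
      res[r] <- if (is.na(v)) {
        f$comparator %in% c("NE", "NOT_CONTAINS")
      } else if (f$comparator %in% c("GE", "GT", "LT", "LE")) {
        vn <- suppressWarnings(as.numeric(v))
        rn <- suppressWarnings(as.numeric(f$reference))
        if (is.na(vn) || is.na(rn)) FALSE
        else switch(f$comparator, GE = vn >= rn, GT = vn > rn,
                    LT = vn < rn, LE = vn <= rn)
      } else if (f$comparator == "EQ") {
        v == f$reference
      } else if (f$comparator == "NE") {
        v != f$reference
      } else if (f$comparator == "CONTAINS") {
        grepl(f$reference, v, fixed = TRUE)
      } else {
        !grepl(f$reference, v, fixed = TRUE)
      }
    }
    keep <- keep & res
  }
  df$ID[keep]
}

# -- CAS checksum recomputed from scratch ----------------------------------
oracle_cas_valid <- function(cas) {
  if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)) return(FALSE)
  d <- as.integer(strsplit(gsub("-", "", cas), "")[[1]])
  n <- length(d)
  acc <- 0L
  for (pos in seq_len(n - 1L)) acc <- acc + (n - pos) * d[pos]
  acc %% 10L == d[n]
}
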