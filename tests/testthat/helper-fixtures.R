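# Shared fixtures built in code.

# three-exon gene with a skipped middle exon (CE) and an exon-2 retained
# intron variant available on demand
make_ce_gene <- function() {
  gene_model("gCE", "chr1", "+",
             list(t123 = cbind(c(0, 200, 400), c(100, 300, 500)),
                  t13 = cbind(c(0, 400), c(100, 500))))
}

make_ri_gene <- function() {
  gene_model("gRI", "chr1", "+",
             list(spliced = cbind(c(0, 200), c(100, 300)),
                  retained = cbind(0, 300)))
}

seven_species <- function() names(gestation_table())

# all non-constant presence patterns over the 7 species
all_presence_patterns <- function() {
  sp <- seven_species()
  out <- list()
  for (code in 1:(2^7 - 2)) {
    v <- as.logical(bitwAnd(code, 2^(0:6)) > 0)
    names(v) <- sp
    out[[code]] <- v
  }
  out
}

# independent oracle: exhaustive single-event enumeration on the tree,
# written against ape primitives only (no package internals)
oracle_parsimony <- function(presence, tree) {
  n_tip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  presence <- presence[tree$tip.label]
  if (all(presence) || all(!presence)) return(NULL)
  matches <- list()
  for (k in seq_len(nrow(tree$edge))) {
    cl <- sort(tips_below(tree$edge[k, 2]))
    if (identical(cl, sort(names(presence)[presence])))
      matches[[length(matches) + 1]] <- list(event = "gain", clade = cl)
    if (identical(cl, sort(names(presence)[!presence])))
      matches[[length(matches) + 1]] <- list(event = "loss", clade = cl)
  }
  if (length(matches) == 1) matches[[1]] else NULL
}

# independent oracle: naive orthology grouping with plain loops
oracle_ortho <- function(mappings, species, keep = 0.6, edge = 0.6) {
  iou2 <- function(s1, e1, s2, e2) {
    inter <- max(0, min(e1, e2) - max(s1, s2))
    inter / ((e1 - s1) + (e2 - s2) - inter)
  }
  exons <- unique(mappings[, c("exon_id", "species")])
  getm <- function(ex, sp) {
    r <- mappings[mappings$exon_id == ex & mappings$target_species == sp, ]
    if (nrow(r) == 0) NULL else c(r$start[1], r$end[1])
  }
  kept <- character(0)
  for (k in seq_len(nrow(exons))) {
    ok <- TRUE
    for (sp in species) {
      iv <- getm(exons$exon_id[k], sp)
      if (is.null(iv)) { ok <- FALSE; break }
      nat <- mappings[mappings$species == sp &
                        mappings$target_species == sp, ]
      if (nrow(nat) == 0) { ok <- FALSE; break }
      best <- 0
      for (j in seq_len(nrow(nat)))
        best <- max(best, iou2(iv[1], iv[2], nat$start[j], nat$end[j]))
      if (best < keep) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, exons$exon_id[k])
  }
  exons <- exons[exons$exon_id %in% kept, ]
  n <- nrow(exons)
  adj <- matrix(FALSE, n, n)
  if (n > 1) for (p in 1:(n - 1)) for (q in (p + 1):n) {
    if (exons$species[p] == exons$species[q]) next
    ok <- TRUE
    for (sp in species) {
      ia <- getm(exons$exon_id[p], sp); ib <- getm(exons$exon_id[q], sp)
      if (is.null(ia) || is.null(ib) ||
          iou2(ia[1], ia[2], ib[1], ib[2]) <= edge) { ok <- FALSE; break }
    }
    adj[p, q] <- adj[q, p] <- ok
  }
  # connected components by BFS
  comp <- rep(NA_integer_, n); cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  groups <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    sp <- exons$species[idx]
    if (length(idx) == length(species) && setequal(sp, species) &&
        !anyDuplicated(sp))
      groups[[length(groups) + 1]] <- sort(exons$exon_id[idx])
  }
  groups[order(vapply(groups, function(g) g[1], ""))]
}

# random orthology instance across 3-7 species, <= 30 exons
random_ortho_instance <- function(n_species, n_slots, p_noise = 0.3) {
  species <- seven_species()[seq_len(n_species)]
  rows <- list()
  for (slot in seq_len(n_slots)) {
    base <- slot * 1000
    len <- sample(50:150, 1)
    for (sp in species) {
      if (stats::runif(1) < 0.15) next  # missing exon in this species
      ex <- paste0("s", slot, ".", sp)
      for (tsp in species) {
        if (stats::runif(1) < 0.1) next  # missing mapping
        shift <- if (stats::runif(1) < p_noise)
          sample(c(-len, -round(len / 2), round(len / 2), len), 1)
          else sample(-3:3, 1)
        rows[[length(rows) + 1]] <- data.frame(
          exon_id = ex, species = sp, target_species = tsp,
          start = base + shift, end = base + shift + len)
      }
    }
  }
  do.call(rbind, rows)
}
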