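test_that("parsimony dates simple presence patterns", {
  sp <- seven_species()
  mk <- function(pres) setNames(sp %in% pres, sp)
  ev <- parsimony_age(mk("mouse"))
  expect_equal(ev$event, "gain")
  expect_equal(ev$age_class, "mouse-specific")
  ev2 <- parsimony_age(mk(c("human", "macaque", "mouse", "rat", "rabbit")))
  expect_equal(ev2$event, "gain")
  expect_equal(ev2$age_class, "eutherian")
  # no single-event explanation
  expect_null(parsimony_age(mk(c("human", "mouse"))))
  # root-split ambiguity: gain on mammal stem vs loss in chicken
  expect_null(parsimony_age(mk(setdiff(sp, "chicken"))))
  # loss: everything except rodents
  ev3 <- parsimony_age(mk(setdiff(sp, c("mouse", "rat"))))
  expect_equal(ev3$event, "loss")
  expect_equal(ev3$age_class, "rodent")
})

test_that("parsimony agrees with the exhaustive oracle on all 126 patterns", {
  tree <- default_species_tree()
  pats <- all_presence_patterns()
  n_datable <- 0
  for (pres in pats) {
    got <- parsimony_age(pres, tree)
    want <- oracle_parsimony(pres, tree)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$event, want$event)
      expect_equal(sort(got$clade), want$clade)
      n_datable <- n_datable + 1
    }
  }
  expect_equal(length(pats), 126L)
  expect_gt(n_datable, 0)
})

test_that("reversing presence labels swaps gain and loss", {
  tree <- default_species_tree()
  for (pres in all_presence_patterns()) {
    a <- parsimony_age(pres, tree)
    b <- parsimony_age(!pres, tree)
    if (!is.null(a) && !is.null(b)) {
      expect_equal(sort(a$clade), sort(b$clade))
      expect_true(a$event != b$event)
    }
  }
})

test_that("seq_similar detects shared blocks and rejects unrelated pairs", {
  set.seed(12)
  s <- random_flanks(1, 60)
  expect_true(seq_similar(s, s))
  # exact 20-nt shared block embedded in otherwise unrelated sequence
  core <- substr(s, 20, 39)
  target <- paste0(strrep("A", 50), core, strrep("A", 50))
  expect_true(seq_similar(s, target))
  # constructed to share no 8-mer: query over A/C, target over G/T
  q <- paste(sample(c("A", "C"), 60, TRUE), collapse = "")
  t <- paste(sample(c("G", "T"), 200, TRUE), collapse = "")
  expect_false(seq_similar(q, t))
  expect_false(seq_similar(q, ""))
  expect_false(seq_similar(NA_character_, t))
})

test_that("interspaced candidates respect single-exon and presence rules", {
  borders <- data.frame(
    pair_id = rep(c("p1", "p2", "p3"), each = 2),
    species = rep(c("human", "mouse"), 3),
    n_between = c(1L, 0L,  0L, 0L,  2L, 0L))
  expect_message(cands <- find_interspaced_candidates(borders), "multi-exon")
  expect_equal(length(cands), 1L)
  expect_equal(cands[[1]]$pair_id, "p1")
  expect_equal(cands[[1]]$presence, c(human = TRUE, mouse = FALSE))
})

test_that("birth filters reject similarity leaks, misaligned pairs, long exons", {
  set.seed(21)
  scen <- generate_evolution_scenario(
    list(list(type = "gain", clade = c("mouse", "rat"))), seed = 5)[[1]]
  cand <- find_interspaced_candidates(scen$borders)[[1]]
  expect_true(apply_birth_filters(cand))

  # filter 1: plant the candidate sequence into an absence species region
  leak <- cand
  absent <- which(!leak$presence[leak$rows$species])[1]
  leak$rows$between_seq[absent] <-
    paste0(leak$rows$between_seq[absent],
           leak$rows$exon_seq[leak$rows$species == "mouse"])
  expect_false(apply_birth_filters(leak))

  # filter 2: presence exons that do not align to each other
  mis <- cand
  pres_idx <- which(mis$presence[mis$rows$species])
  mis$rows$exon_seq[pres_idx[2]] <-
    paste(rep(c("G", "T"), 34), collapse = "")
  expect_false(apply_birth_filters(mis))

  # filter 3: length >= 500
  long <- cand
  long$rows$exon_len[pres_idx] <- 520L
  expect_false(apply_birth_filters(long))
})

test_that("alternification applies the 4-pairs-below-0.9 rule strictly", {
  sp <- seven_species()
  mk_tables <- function(n_below_mouse) {
    lapply(setNames(sp, sp), function(s) {
      if (s == "mouse") c(rep(0.85, n_below_mouse),
                          rep(0.95, 14 - n_below_mouse))
      else rep(0.95, 14)
    })
  }
  alt4 <- detect_alternification(mk_tables(4))
  expect_equal(unname(alt4$status["mouse"]), "cassette")
  expect_equal(alt4$event$event, "alternification_gain")
  expect_equal(alt4$event$age_class, "mouse-specific")
  alt3 <- detect_alternification(mk_tables(3))
  expect_equal(unname(alt3$status["mouse"]), "constitutive")
  expect_null(alt3$event)  # constant vector: no event
  # species with no defined PSI -> record discarded
  tabs <- mk_tables(4); tabs$rat <- rep(NA_real_, 14)
  expect_null(detect_alternification(tabs))
})

test_that("planted events are recovered over 200 seeded scenarios", {
  tree <- default_species_tree()
  # root-child clades (chicken / the mammal stem) are excluded: patterns
  # on either side of the root are single-event ambiguous by design
  clades <- list("mouse", "opossum", c("human", "macaque"),
                 c("mouse", "rat"), c("mouse", "rat", "rabbit"),
                 c("human", "macaque", "mouse", "rat", "rabbit"))
  set.seed(606)
  events <- lapply(1:200, function(k)
    list(type = sample(c("gain", "loss", "alternification_gain"), 1),
         clade = clades[[sample(length(clades), 1)]]))
  scen <- generate_evolution_scenario(events, tree, seed = 607)
  ok <- vapply(seq_along(scen), function(k) {
    sc <- scen[[k]]
    if (sc$type %in% c("gain", "loss")) {
      cand <- find_interspaced_candidates(sc$borders)[[1]]
      if (!apply_birth_filters(cand)) return(FALSE)
      ev <- parsimony_age(cand$presence, tree)
      !is.null(ev) && ev$event == sc$type &&
        identical(sort(ev$clade), sc$truth$clade)
    } else {
      alt <- detect_alternification(sc$psi_tables, tree)
      !is.null(alt$event) && alt$event$event == sc$type &&
        identical(sort(alt$event$clade), sc$truth$clade)
    }
  }, TRUE)
  expect_equal(mean(ok), 1)
})

test_that("interval_overlap_flag honours the minimum overlap", {
  te <- rbind(c(100, 200))
  expect_false(interval_overlap_flag(c(191, 250), te, min_overlap = 10))
  expect_true(interval_overlap_flag(c(190, 250), te, min_overlap = 10))
  expect_true(interval_overlap_flag(c(120, 150), te, min_overlap = 10))
  expect_true(interval_overlap_flag(c(199, 250), te, min_overlap = 1))
  expect_false(interval_overlap_flag(c(50, 60), te))
})
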