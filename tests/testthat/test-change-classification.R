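all_state_vectors <- function(k) {
  do.call(expand.grid, c(rep(list(c("0", "1", "?")), k),
                         stringsAsFactors = FALSE))
}

test_that("per-bin change labels follow the ancestor/descendant rules", {
  expect_equal(classify_bins(c("1", "1", "0"), c("1", "0", "1")),
               c("stasis", "retraction", "expansion"))
  expect_equal(classify_bins(c("?", "1"), c("1", "1")),
               c("indeterminate", "stasis"))
  expect_error(classify_bins(c("1"), c("1", "0")), "length")
  expect_error(classify_bins("2", "1"), "states")
})

test_that("per-bin labels agree with the independent rule oracle exhaustively", {
  for (k in 1:3) {
    vs <- all_state_vectors(k)
    for (i in seq_len(nrow(vs))) for (j in seq_len(nrow(vs))) {
      A <- as.character(vs[i, ]); D <- as.character(vs[j, ])
      got <- classify_bins(A, D)
      expect_identical(got, oracle_classify_bins(A, D))
      # swap symmetry: expansion <-> retraction
      sw <- classify_bins(D, A)
      expect_identical(sw == "expansion", got == "retraction")
      expect_identical(sw == "retraction", got == "expansion")
    }
  }
})

test_that("event typology anchors to the ancestral present run", {
  A <- rep("0", 10); A[4:7] <- "1"          # present bins 4..7
  D_hi <- A; D_hi[8:9] <- "1"
  expect_equal(classify_events(A, D_hi)$events, "expansion_high")
  D_lo <- A; D_lo[4] <- "0"
  expect_equal(classify_events(A, D_lo)$events, "retraction_low")
  D_shift <- rep("0", 10); D_shift[9:10] <- "1"
  ev <- classify_events(A, D_shift)
  expect_setequal(ev$events, c("complete_retraction", "expansion_high"))
  D_both <- rep("0", 10); D_both[3:6] <- "1"
  expect_setequal(classify_events(A, D_both)$events,
                  c("expansion_low", "retraction_high"))
  # interior changes get their own labels, never high/low
  D_hole <- A; D_hole[5] <- "0"
  expect_equal(classify_events(A, D_hole)$events, "interior_retraction")
  # ancestor with no certain presence
  expect_equal(classify_events(rep("?", 4), c("1", "1", "0", "0"))$events,
               "indeterminate_ancestor")
  # stasis when nothing changes
  expect_equal(classify_events(A, A)$events, "stasis")
})

test_that("complete retraction across uncertain ancestral bins is flagged", {
  A <- c("1", "1", "?", "?")
  D <- c("0", "0", "1", "1")
  ev <- classify_events(A, D)
  expect_true("complete_retraction" %in% ev$events)
  expect_true(ev$uncertain_ancestor_overlap)
})

test_that("uncertainty never creates a certain changed bin (indeterminate dominance)", {
  set.seed(14)
  for (rep in 1:60) {
    k <- sample(3:6, 1)
    A <- sample(c("0", "1"), k, replace = TRUE)
    if (!any(A == "1")) A[1] <- "1"
    D <- sample(c("0", "1"), k, replace = TRUE)
    base <- classify_bins(A, D)
    i <- sample(k, 1)
    for (side in 1:2) {
      A2 <- A; D2 <- D
      if (side == 1) A2[i] <- "?" else D2[i] <- "?"
      masked <- classify_bins(A2, D2)
      changed <- masked %in% c("expansion", "retraction")
      base_changed <- base %in% c("expansion", "retraction")
      expect_true(all(!changed | base_changed))
      # and a pure-stasis branch can never acquire an event through masking
      if (all(base == "stasis")) {
        ev <- classify_events(A2, D2)$events
        expect_true(all(ev %in% c("stasis", "indeterminate_ancestor")))
      }
    }
  }
})

test_that("clade summary counts species with changes and in both variables", {
  tree <- simulate_yule_tree(10, seed = 12)
  sc <- structure(list(variable = "temperature", edges = as.numeric(0:8),
                       width = 1, global_min = 0, global_max = 8, n_bins = 8L),
                  class = "bin_scheme")
  sc2 <- sc; sc2$variable <- "precipitation"
  base <- code_br(c(2.2, 5.8), c(0, 8), sc)
  codings_t <- codings_p <- list()
  for (sp in tree$tip.label) { codings_t[[sp]] <- base; codings_p[[sp]] <- base }
  # plant changes: sp01 temp expansion_high; sp02 both variables retraction
  codings_t$sp01 <- code_br(c(2.2, 7.8), c(0, 8), sc)
  codings_t$sp02 <- code_br(c(3.2, 5.8), c(0, 8), sc)
  codings_p$sp02 <- code_br(c(3.2, 5.8), c(0, 8), sc2)
  br_t <- build_br_matrix(codings_t, tree, sc)
  br_p <- build_br_matrix(codings_p, tree, sc2)
  anc <- list(temperature = reconstruct_matrix(br_t, tree),
              precipitation = reconstruct_matrix(br_p, tree))
  out <- summarize_clade(tree, anc, list(temperature = br_t, precipitation = br_p))
  cl <- out$clade
  expect_equal(cl$n_changed_strict[cl$variable == "temperature"], 2)
  expect_equal(cl$n_changed_strict[cl$variable == "precipitation"], 1)
  expect_equal(attr(cl, "both_variables"), "sp02")
  # brute-force set check
  per_var <- attr(cl, "species_changed")
  expect_setequal(intersect(per_var$temperature, per_var$precipitation), "sp02")
  expect_equal(sort(unique(out$changes$species)), sort(tree$tip.label))
})

test_that("no-event truth yields zero changed species", {
  tree <- simulate_yule_tree(5, seed = 3)
  sc <- structure(list(variable = "v", edges = as.numeric(0:6), width = 1,
                       global_min = 0, global_max = 6, n_bins = 6L),
                  class = "bin_scheme")
  codings <- list()
  for (sp in tree$tip.label) codings[[sp]] <- code_br(c(1.5, 4.5), c(0, 6), sc)
  br <- build_br_matrix(codings, tree, sc)
  anc <- list(v = reconstruct_matrix(br, tree))
  out <- summarize_clade(tree, anc, list(v = br))
  expect_equal(out$clade$n_changed_strict, 0)
  expect_true(all(out$changes$events == "stasis"))
})

test_that("recovery scoring matches reported events against truth keys", {
  changes <- data.frame(
    species = c("sp1", "sp2", "sp3"),
    variable = "temperature",
    events = c("expansion_high", "stasis", "retraction_low;expansion_high"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    parent = "n5", child = c("sp1", "sp3"),
    variable = "temperature",
    event = c("expansion_high", "retraction_low"),
    stringsAsFactors = FALSE)
  sc <- score_recovery(changes, truth)
  expect_equal(sc$sensitivity, 1.0)
  pc <- sc$per_class
  expect_equal(pc$n_spurious[pc$class == "expansion_high"], 1)  # sp3 extra event
  expect_equal(sc$fdp, 1 / 3)
})
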