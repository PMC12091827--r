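#' Classify per-bin niche changes between ancestor and descendant
#'
#' Certain present in the ancestor and certain absent in the descendant is
#' a retraction; certain absent in the ancestor and certain present in the
#' descendant is an expansion; identical certain states are stasis; any
#' pair involving an uncertain state is indeterminate.
#'
#' @param A,D character vectors over `{"1", "0", "?"}` of equal length
#'   (ancestor and descendant bin states).
#' @return character vector over
#'   `{"stasis", "retraction", "expansion", "indeterminate"}`.
#' @export
classify_bins <- function(A, D) {
  if (length(A) != length(D)) stop_invalid("ancestor/descendant vectors differ in length")
  bad <- !(A %in% c("0", "1", "?")) | !(D %in% c("0", "1", "?"))
  if (any(bad)) stop_invalid("bin states must be '1', '0' or '?'")
  out <- rep("indeterminate", length(A))
  certain <- A != "?" & D != "?"
  out[certain & A == D] <- "stasis"
  out[certain & A == "1" & D == "0"] <- "retraction"
  out[certain & A == "0" & D == "1"] <- "expansion"
  out
}

#' Classify branch-level niche-change events
#'
#' Anchored to the ancestor's certain-present run: expansions strictly
#' above its highest present bin are `expansion_high`, strictly below its
#' lowest are `expansion_low`, and changes strictly inside the run are
#' `interior_*`. A retraction run containing the ancestor's highest
#' (lowest) present bin is `retraction_high` (`retraction_low`). When the
#' descendant shares no certain-present bin with the ancestor the change
#' is reported as `complete_retraction` (replacing the per-limit
#' retraction labels; any expansions are still reported), with a note when
#' the descendant's present bins overlap only uncertain ancestral bins.
#'
#' @inheritParams classify_bins
#' @return list: `events` (character vector), `per_bin` (from
#'   [classify_bins()]), `n_changed_bins`, `uncertain_ancestor_overlap`
#'   (logical: the complete retraction coincides with uncertainty in the
#'   ancestral states at the descendant's present bins).
#' @export
classify_events <- function(A, D) {
  per_bin <- classify_bins(A, D)
  pa <- which(A == "1")
  pd <- which(D == "1")
  n_changed <- sum(per_bin %in% c("expansion", "retraction"))
  if (!length(pa)) {
    return(list(events = "indeterminate_ancestor", per_bin = per_bin,
                n_changed_bins = n_changed, uncertain_ancestor_overlap = FALSE))
  }
  lo <- min(pa); hi <- max(pa)
  events <- character(0)
  exp_bins <- which(per_bin == "expansion")
  if (any(exp_bins > hi)) events <- c(events, "expansion_high")
  if (any(exp_bins < lo)) events <- c(events, "expansion_low")
  if (any(exp_bins > lo & exp_bins < hi)) events <- c(events, "interior_expansion")
  complete <- length(pd) > 0 && !any(pd %in% pa)
  uncertain_overlap <- complete && any(A[pd] == "?")
  ret_bins <- which(per_bin == "retraction")
  if (complete) {
    events <- c(events, "complete_retraction")
  } else if (length(ret_bins)) {
    runs <- split(ret_bins, cumsum(c(1, diff(ret_bins) != 1)))
    for (r in runs) {
      is_high <- hi %in% r
      is_low <- lo %in% r
      if (is_high) events <- c(events, "retraction_high")
      if (is_low) events <- c(events, "retraction_low")
      if (!is_high && !is_low) events <- c(events, "interior_retraction")
    }
  }
  if (!length(events)) events <- "stasis"
  list(events = unique(events), per_bin = per_bin, n_changed_bins = n_changed,
       uncertain_ancestor_overlap = uncertain_overlap)
}

#' Summarize niche changes over the clade
#'
#' Compares, for every terminal branch and variable, the reconstructed
#' ancestral bin vector of the tip's parent with the tip's observed BR
#' vector, and tallies species-level change counts. Strict counts include
#' only species with at least one certain change bin; inclusive counts
#' additionally count complete non-utilization of ancestral conditions
#' inferred across uncertain ancestral bins.
#'
#' @param tree dated `phylo`.
#' @param ancestral named list (variable -> `ancestral_niche`).
#' @param tips named list (variable -> `br_matrix`).
#' @return list: `changes` (data.frame: one row per species x variable,
#'   sorted by species) and `clade` (data.frame of per-variable counts:
#'   species with any certain change, plus a `both` attribute row).
#' @export
summarize_clade <- function(tree, ancestral, tips) {
  vars <- names(ancestral)
  labs <- node_labels(tree)
  ntip <- ape::Ntip(tree)
  rows <- list()
  for (v in vars) {
    anc <- ancestral[[v]]
    br <- tips[[v]]
    mids <- bin_midpoints(attr(br, "scheme"))
    for (i in seq_len(ntip)) {
      sp <- tree$tip.label[i]
      par <- tree$edge[tree$edge[, 2] == i, 1]
      A <- anc$state[labs[par], ]
      Dv <- br[sp, ]
      cl <- classify_events(A, Dv)
      chbins <- which(cl$per_bin %in% c("expansion", "retraction"))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, variable = v,
        events = paste(cl$events, collapse = ";"),
        n_changed_bins = cl$n_changed_bins,
        changed_range = if (length(chbins)) {
          sprintf("%.6g-%.6g", min(mids[chbins]), max(mids[chbins]))
        } else "",
        has_change = any(cl$per_bin %in% c("expansion", "retraction")),
        complete_retraction = "complete_retraction" %in% cl$events,
        uncertain_ancestor_overlap = cl$uncertain_ancestor_overlap,
        stringsAsFactors = FALSE)
    }
  }
  changes <- do.call(rbind, rows)
  changes <- changes[order(changes$species, changes$variable), ]
  rownames(changes) <- NULL
  per_var <- lapply(vars, function(v) {
    ch <- changes[changes$variable == v, ]
    strict <- ch$species[ch$has_change]
    inclusive <- ch$species[ch$has_change | ch$complete_retraction]
    data.frame(variable = v,
               n_species = ntip,
               n_changed_strict = length(unique(strict)),
               n_changed_inclusive = length(unique(inclusive)),
               stringsAsFactors = FALSE)
  })
  clade <- do.call(rbind, per_var)
  changed_sets <- lapply(vars, function(v) {
    ch <- changes[changes$variable == v, ]
    unique(ch$species[ch$has_change])
  })
  both <- if (length(vars) >= 2) Reduce(intersect, changed_sets) else character(0)
  attr(clade, "species_changed") <- stats::setNames(changed_sets, vars)
  attr(clade, "both_variables") <- both
  list(changes = changes, clade = clade)
}

#' Score recovery of planted truth events
#'
#' Matches reported terminal-branch events against the generator's truth
#' table on (species, variable, event class): sensitivity is the fraction
#' of true events recovered, and the false-discovery proportion (FDP) is
#' the fraction of reported certain events with no matching truth.
#'
#' @param changes the `changes` table from [summarize_clade()].
#' @param truth truth-event data.frame from [evolve_true_niches()]
#'   (terminal-branch rows are selected by `child %in% species`).
#' @param classes event classes to score.
#' @return list: `per_class` data.frame (class, n_true, n_recovered,
#'   n_reported, n_spurious, sensitivity, fdp), plus overall `sensitivity`
#'   and `fdp`.
#' @export
score_recovery <- function(changes, truth,
                           classes = c("expansion_high", "expansion_low",
                                       "retraction_high", "retraction_low")) {
  species <- unique(changes$species)
  tt <- truth[truth$child %in% species & truth$event %in% classes, , drop = FALSE]
  reported <- do.call(rbind, lapply(seq_len(nrow(changes)), function(i) {
    evs <- strsplit(changes$events[i], ";", fixed = TRUE)[[1]]
    evs <- intersect(evs, classes)
    if (!length(evs)) return(NULL)
    data.frame(species = changes$species[i], variable = changes$variable[i],
               event = evs, stringsAsFactors = FALSE)
  }))
  if (is.null(reported)) {
    reported <- data.frame(species = character(0), variable = character(0),
                           event = character(0))
  }
  key <- function(d, sp, v, e) paste(d[[sp]], d[[v]], d[[e]])
  truth_keys <- paste(tt$child, tt$variable, tt$event)
  rep_keys <- key(reported, "species", "variable", "event")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tk <- truth_keys[tt$event == cl]
    rk <- rep_keys[reported$event == cl]
    data.frame(class = cl,
               n_true = length(tk),
               n_recovered = sum(tk %in% rk),
               n_reported = length(rk),
               n_spurious = sum(!(rk %in% tk)),
               sensitivity = if (length(tk)) sum(tk %in% rk) / length(tk) else NA_real_,
               fdp = if (length(rk)) sum(!(rk %in% tk)) / length(rk) else 0,
               stringsAsFactors = FALSE)
  }))
  n_true <- sum(per_class$n_true)
  n_rec <- sum(per_class$n_recovered)
  n_rep <- sum(per_class$n_reported)
  n_spur <- sum(per_class$n_spurious)
  list(per_class = per_class,
       sensitivity = if (n_true) n_rec / n_true else NA_real_,
       fdp = if (n_rep) n_spur / n_rep else 0,
       n_branches = length(species))
}
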