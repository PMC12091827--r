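#' Simulate a complete synthetic niche-evolution study
#'
#' Generates everything a full analysis consumes, with known ground truth:
#' two orthogonal environmental gradients (temperature north-south,
#' precipitation west-east) on one frame, a dated Yule tree, true interval
#' niches evolved along the tree with recorded expansion/retraction
#' events, and per-species occurrence samples drawn from the jointly
#' suitable cells. Defaults mirror the study design this package targets:
#' a 40-species clade, 6.12 Myr crown age, 8 species left to be
#' characterized from occurrences only, and per-species record counts
#' between 2 and 54.
#'
#' Events are planted on terminal branches of the simulable species only:
#' species characterized from occurrences alone carry coding uncertainty
#' that makes retraction events structurally unrecoverable, so planting
#' truth there would conflate generator design with method performance.
#'
#' @param n_species number of tips.
#' @param n_rows,n_cols grid dimensions.
#' @param depth crown age, Myr.
#' @param noise_sd named vector of grid noise SDs (temperature degC,
#'   precipitation mm); 0 gives exact gradients.
#' @param event_rate per-terminal-branch, per-variable event probability.
#' @param step_sd named vector of event magnitude scales.
#' @param min_magnitude floor on event magnitudes (same units as each
#'   variable; scales with the variable via `step_sd` proportions when a
#'   single number is given times the bin width — pass a named vector for
#'   full control).
#' @param n_low_record number of species forced to occurrence-only status.
#' @param records `"paper"` draws per-species record counts from a
#'   right-skewed distribution clamped to [2, 54] (low-record species get
#'   2-4); `"dense"` samples every jointly suitable cell per species.
#' @param events `"random"` draws events per terminal branch with
#'   probability `event_rate`; `"one_per_class"` plants exactly one event
#'   of each class (expansion/retraction at the upper/lower limit) per
#'   variable, each on a different species, so the four changed spectral
#'   zones are disjoint — the identifiable-recovery design used for
#'   validation.
#' @param event_classes event classes planted under `"one_per_class"`;
#'   restricting to the retraction classes keeps every changed zone inside
#'   the clade's shared environmental range, where ancestors stay certain
#'   even under realistic accessible-area truncation.
#' @param min_branch_frac events are planted only on terminal branches at
#'   least this fraction of the crown age: a change on a near-zero-length
#'   branch leaves essentially no time for evolution and is statistically
#'   unidentifiable.
#' @param root_intervals named list of root `c(low, high)` intervals; the
#'   defaults sit at bin-width centers so interval limits do not coincide
#'   with bin edges.
#' @param seed master seed; all stage seeds derive from it.
#' @return list: `grids`, `tree`, `truth`, `occurrences`,
#'   `low_record_species`, `bin_widths`, `params`.
#' @export
simulate_study <- function(n_species = 40, n_rows = 100, n_cols = 100,
                           depth = 6.12,
                           noise_sd = c(temperature = 0, precipitation = 0),
                           event_rate = 0.3,
                           step_sd = c(temperature = 4, precipitation = 400),
                           min_magnitude = c(temperature = 0, precipitation = 0),
                           max_magnitude = c(temperature = Inf, precipitation = Inf),
                           n_low_record = 8,
                           records = c("paper", "dense"),
                           events = c("random", "one_per_class"),
                           event_classes = c("expansion_high", "expansion_low",
                                             "retraction_high", "retraction_low"),
                           min_branch_frac = 0.05,
                           root_intervals = list(temperature = c(12.5, 19.5),
                                                 precipitation = c(1250, 1950)),
                           seed = 1) {
  events <- match.arg(events)
  records <- match.arg(records)
  check_count(n_species, "n_species", min = 2L)
  if (n_low_record >= n_species) stop_invalid("`n_low_record` must be < `n_species`")
  grid_ranges <- list(temperature = c(0, 30), precipitation = c(0, 3000))
  bin_widths <- c(temperature = 1, precipitation = 100)
  grids <- list(
    temperature = simulate_env_grid(
      n_rows, n_cols, gradient = list(direction = "ns", range = grid_ranges$temperature),
      noise_sd = noise_sd[["temperature"]], seed = seed * 13 %% 2147483647,
      variable = "temperature", xll = -65, yll = -45, cellsize = 0.25),
    precipitation = simulate_env_grid(
      n_rows, n_cols, gradient = list(direction = "we", range = grid_ranges$precipitation),
      noise_sd = noise_sd[["precipitation"]], seed = seed * 17 %% 2147483647,
      variable = "precipitation", xll = -65, yll = -45, cellsize = 0.25))
  ## the identifiable-recovery design needs four identifiable terminal
  ## branches outside the occurrence-only set; Yule trees occasionally
  ## lack them, in which case the tree is redrawn deterministically
  tree <- NULL
  for (attempt in 0:19) {
    tseed <- (seed + attempt * 7919) %% 2147483647
    cand <- simulate_yule_tree(n_species, depth = depth, seed = tseed)
    lr <- with_seed(tseed + 1, sample(cand$tip.label, n_low_record))
    if (events == "random") {
      bt <- branch_table(cand)
      long_enough <- bt$child[bt$is_terminal &
                                bt$length >= min_branch_frac * depth]
      elig <- intersect(setdiff(cand$tip.label, lr), long_enough)
      tree <- cand; low_record <- lr; eligible <- elig
      break
    }
    elig <- setdiff(identifiable_tips(cand), lr)
    if (length(elig) >= length(niche_event_types)) {
      tree <- cand; low_record <- lr; eligible <- elig
      break
    }
  }
  if (is.null(tree)) {
    stop_invalid("no tree with %d identifiable terminal branches found",
                 length(niche_event_types))
  }
  if (is.null(names(min_magnitude))) {
    min_magnitude <- c(temperature = min_magnitude[[1]] * bin_widths[["temperature"]],
                       precipitation = min_magnitude[[1]] * bin_widths[["precipitation"]])
  }
  ## a niche must keep at least two bin widths so its occupied range spans
  ## several grid values on the 100-cell gradients
  min_width <- 2 * bin_widths
  truth <- if (events == "one_per_class") {
    plant_one_per_class(tree, root_intervals, grid_ranges, eligible,
                        step_sd, min_magnitude, max_magnitude, seed + 2,
                        min_width, classes = event_classes)
  } else {
    evolve_true_niches(
      tree, root_intervals, grid_ranges, event_rate = event_rate,
      step_sd = as.list(step_sd), seed = seed + 2,
      min_magnitude = 0, min_width = min_width,
      terminal_only = TRUE, eligible_tips = eligible)
  }
  ## apply per-variable magnitude floors/caps by re-deriving child intervals
  if ((any(min_magnitude > 0) || any(is.finite(max_magnitude))) &&
      nrow(truth$events)) {
    ev <- truth$events
    for (i in seq_len(nrow(ev))) {
      if (ev$clamped[i]) next
      v <- ev$variable[i]
      m <- min(max(ev$magnitude_applied[i], min_magnitude[[v]]), max_magnitude[[v]])
      ev$magnitude[i] <- ev$magnitude_applied[i] <- m
    }
    truth$events <- ev
    truth$niches <- replay_events(tree, root_intervals, ev, grid_ranges)
  }
  occ <- list()
  for (i in seq_along(tree$tip.label)) {
    sp <- tree$tip.label[i]
    niche <- list(
      temperature = unlist(truth$niches[truth$niches$node == sp &
                                          truth$niches$variable == "temperature",
                                        c("low", "high")]),
      precipitation = unlist(truth$niches[truth$niches$node == sp &
                                            truth$niches$variable == "precipitation",
                                          c("low", "high")]))
    k <- if (records == "dense") NULL else with_seed(seed + 100 + i, {
      if (sp %in% low_record) sample(2:4, 1)
      else min(54L, max(5L, round(stats::rlnorm(1, log(11), 0.7))))
    })
    occ[[i]] <- sample_occurrences(grids, niche, k = k, species = sp,
                                   seed = seed + 200 + i)
  }
  occurrences <- do.call(rbind, occ)
  list(grids = grids, tree = tree, truth = truth, occurrences = occurrences,
       low_record_species = low_record, bin_widths = bin_widths,
       params = list(seed = seed, event_rate = event_rate, step_sd = step_sd,
                     records = records, root_intervals = root_intervals,
                     grid_ranges = grid_ranges))
}

#' Identifiable terminal branches of a dated tree
#'
#' A niche change on a terminal branch is recoverable only if, when the
#' tip's state differs from every other tip, the maximum-likelihood
#' reconstruction still calls the tip's parent with certainty (so the
#' change is attributed to that branch and not smeared over its
#' neighbourhood). This probe computes that condition directly: for each
#' tip it reconstructs the single-deviant character and keeps the tip if
#' the parent is certain at threshold `theta`. Near-root branches, cherry
#' branches with long stems, and near-zero-length branches fail the
#' probe — the identifiability floor of binned-character reconstruction.
#'
#' @param tree dated `phylo`.
#' @param theta discretization threshold used downstream.
#' @return character vector of tip labels on identifiable branches.
#' @export
identifiable_tips <- function(tree, theta = 0.8) {
  tree <- validate_dated_tree(tree)
  ntip <- ape::Ntip(tree)
  labs <- node_labels(tree)
  keep <- character(0)
  for (i in seq_len(ntip)) {
    probe <- stats::setNames(rep("1", ntip), tree$tip.label)
    probe[i] <- "0"
    fit <- estimate_rate(tree, probe)
    ms <- marginal_states(tree, probe, fit$rate, theta = theta)
    par <- tree$edge[tree$edge[, 2] == i, 1]
    if (ms$state[labs[par]] == "1") keep <- c(keep, tree$tip.label[i])
  }
  keep
}

## exactly one event of each class per variable, each on a distinct
## eligible tip, magnitudes |N(0, sd)| floored/capped
plant_one_per_class <- function(tree, root_intervals, grid_ranges, eligible,
                                step_sd, min_magnitude, max_magnitude, seed,
                                min_width, classes = niche_event_types) {
  vars <- names(root_intervals)
  if (length(eligible) < length(classes)) {
    stop_invalid("only %d eligible tips for %d event classes",
                 length(eligible), length(classes))
  }
  labs <- node_labels(tree)
  bt <- branch_table(tree)
  ev <- list()
  with_seed(seed, {
    for (v in vars) {
      carriers <- sample(eligible, length(classes))
      order_cl <- sample(classes)
      for (j in seq_along(classes)) {
        m <- abs(stats::rnorm(1, 0, step_sd[[v]]))
        m <- min(max(m, min_magnitude[[v]]), max_magnitude[[v]])
        ev[[length(ev) + 1L]] <- data.frame(
          parent = bt$parent[bt$child == carriers[j]],
          child = carriers[j], variable = v, event = order_cl[j],
          magnitude = m, magnitude_applied = m, clamped = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  })
  events <- do.call(rbind, ev)
  ## validity: retractions must leave a positive width; magnitudes beyond
  ## the grid range are clamped with a record
  for (i in seq_len(nrow(events))) {
    v <- events$variable[i]
    iv <- root_intervals[[v]]; gr <- grid_ranges[[v]]
    a <- events$magnitude_applied[i]
    if (events$event[i] %in% c("retraction_high", "retraction_low") &&
        a > (iv[2] - iv[1]) - min_width[[v]]) {
      events$magnitude_applied[i] <- (iv[2] - iv[1]) - min_width[[v]]
      events$clamped[i] <- TRUE
    }
    if (events$event[i] == "expansion_high" && iv[2] + a > gr[2]) {
      events$magnitude_applied[i] <- gr[2] - iv[2]
      events$clamped[i] <- TRUE
    }
    if (events$event[i] == "expansion_low" && iv[1] - a < gr[1]) {
      events$magnitude_applied[i] <- iv[1] - gr[1]
      events$clamped[i] <- TRUE
    }
  }
  list(niches = replay_events(tree, root_intervals, events, grid_ranges),
       events = events)
}

## recompute all node intervals from the root plus an event table
replay_events <- function(tree, root_intervals, events, grid_ranges) {
  labs <- node_labels(tree)
  vars <- names(root_intervals)
  po <- ape::reorder.phylo(tree, "postorder")
  niche <- array(NA_real_, dim = c(length(labs), length(vars), 2),
                 dimnames = list(labs, vars, c("low", "high")))
  root <- ape::Ntip(tree) + 1L
  for (v in vars) niche[labs[root], v, ] <- root_intervals[[v]]
  for (ei in rev(seq_len(nrow(po$edge)))) {
    pid <- po$edge[ei, 1]; cid <- po$edge[ei, 2]
    for (v in vars) {
      iv <- niche[labs[pid], v, ]
      e <- events[events$parent == labs[pid] & events$child == labs[cid] &
                    events$variable == v, ]
      if (nrow(e) == 1) {
        a <- e$magnitude_applied
        iv <- switch(e$event,
          expansion_high = c(iv[1], iv[2] + a),
          expansion_low = c(iv[1] - a, iv[2]),
          retraction_high = c(iv[1], iv[2] - a),
          retraction_low = c(iv[1] + a, iv[2]))
        gr <- grid_ranges[[v]]
        iv <- c(max(iv[1], gr[1]), min(iv[2], gr[2]))
      }
      niche[labs[cid], v, ] <- iv
    }
  }
  data.frame(
    node = rep(labs, times = length(vars)),
    variable = rep(vars, each = length(labs)),
    low = as.vector(niche[, , "low"]),
    high = as.vector(niche[, , "high"]),
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' thinning threshold 5.2 km, 35 dispersal events with at most 2
#' dispersers and kernel SD 0.50, chi-square suitability truncation 0.95,
#' minimum 5 records for M simulation, bin widths of 1 degC
#' (temperature) and 100 mm (precipitation), ancestral-state threshold
#' 0.8.
#'
#' @param grids named list of [env_grid()]s (or paths readable by
#'   [read_env_grid()]).
#' @param occurrences occurrence data.frame (or CSV path).
#' @param tree dated `phylo` (or Newick path).
#' @param out_dir output directory (`NULL` for no file output).
#' @param bin_widths named numeric vector of bin widths per variable.
#' @param thin_km spatial thinning threshold, km; `NULL` disables thinning.
#' @param m_config a [dispersal_config()].
#' @param truncation_q,min_records suitability-envelope parameters.
#' @param theta ancestral-state discretization threshold.
#' @param rate_bounds ML rate search bounds, per Myr.
#' @param force_occurrence_only species labels to characterize from
#'   occurrence points only, regardless of record count.
#' @param m_mode `"simulate"` runs the dispersal simulation per species;
#'   `"full"` treats the whole data frame as accessible to every species —
#'   a no-truncation baseline useful when validating the coding and
#'   reconstruction stages in isolation.
#' @param seed master seed for the M simulations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(grids, occurrences, tree, out_dir = NULL,
                            bin_widths = c(temperature = 1, precipitation = 100),
                            thin_km = 5.2,
                            m_config = dispersal_config(),
                            truncation_q = 0.95, min_records = 5,
                            theta = 0.8, rate_bounds = c(1e-8, 1e3),
                            force_occurrence_only = character(0),
                            m_mode = c("simulate", "full"),
                            seed = 1) {
  m_mode <- match.arg(m_mode)
  if (is.character(grids)) {
    grids <- stats::setNames(lapply(grids, read_env_grid), NULL)
    names(grids) <- vapply(grids, function(g) g$variable, character(1))
  }
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  if (is.character(tree)) tree <- read_dated_tree(tree)
  tree <- validate_dated_tree(tree)
  assert_shared_frame(grids)
  if (!all(names(bin_widths) %in% names(grids))) {
    stop_invalid("bin widths given for variables without grids: %s",
                 paste(setdiff(names(bin_widths), names(grids)), collapse = ", "))
  }
  if (any(bin_widths <= 0)) stop_invalid("bin widths must be > 0")
  structure(list(grids = grids, occurrences = occurrences, tree = tree,
                 out_dir = out_dir, bin_widths = bin_widths, thin_km = thin_km,
                 m_config = m_config, truncation_q = truncation_q,
                 min_records = min_records, theta = theta,
                 rate_bounds = rate_bounds,
                 force_occurrence_only = force_occurrence_only,
                 m_mode = m_mode, seed = seed),
            class = "pipeline_config")
}

#' Run the full niche-evolution analysis
#'
#' Stages, in order: occurrence validation, spatial thinning, accessible
#' area (M) construction per species, clade-wide bin schemes within the
#' union of all Ms, BR character coding, maximum-likelihood ancestral
#' reconstruction per variable, branch-wise change classification and
#' clade summary, and geographic projection for species with changes.
#' When `out_dir` is set, every product is written (occurrence CSV, 0/1
#' mask rasters, BR and ancestral-state TSVs, change tables, category
#' rasters) and listed in a manifest with content hashes; reruns with the
#' same config reproduce the hashes.
#'
#' @param config a [pipeline_config()].
#' @return list: `occurrences` (validated, thinned), `areas`, `schemes`,
#'   `br`, `ancestral`, `summary` (from [summarize_clade()]),
#'   `projections`, `niche_summaries`, `log` (per-stage counts),
#'   `manifest` (when writing).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  grids <- config$grids
  tree <- config$tree
  frame <- grids[[1]]
  vars <- names(config$bin_widths)
  log <- list()

  occ <- validate_occurrences(config$occurrences, frame)
  log$n_records_in <- nrow(config$occurrences)
  log$n_records_valid <- nrow(occ)
  if (!is.null(config$thin_km)) {
    occ <- thin_occurrences(occ, min_dist_km = config$thin_km, frame = frame)
  }
  log$n_records_thinned <- nrow(occ)
  species <- tree$tip.label
  missing <- setdiff(species, unique(occ$species))
  if (length(missing)) {
    stop_invalid("tree tips without occurrences: %s", paste(missing, collapse = ", "))
  }

  areas <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    so <- occ[occ$species == sp, , drop = FALSE]
    if (identical(config$m_mode, "full") &&
        !(sp %in% config$force_occurrence_only)) {
      data_mask <- !is.na(frame$values)
      for (v in vars) data_mask <- data_mask & !is.na(grids[[v]]$values)
      areas[[sp]] <- structure(list(species = sp, mask = data_mask,
                                    status = "simulated"),
                               class = "accessible_area")
    } else if (sp %in% config$force_occurrence_only) {
      rc <- point_to_cell(frame, so$longitude, so$latitude)
      mask <- matrix(FALSE, n_rows(frame), n_cols(frame))
      mask[cbind(rc$row, rc$col)] <- TRUE
      areas[[sp]] <- structure(list(species = sp, mask = mask,
                                    status = "occurrence_only"),
                               class = "accessible_area")
    } else {
      cfg <- config$m_config
      cfg$seed <- (config$seed + i) %% 2147483647
      areas[[sp]] <- build_m_or_fallback(so, grids[vars], cfg,
                                         truncation_q = config$truncation_q,
                                         min_records = config$min_records)
    }
  }
  log$n_occurrence_only <- sum(vapply(areas, function(a) a$status == "occurrence_only",
                                      logical(1)))

  union <- union_mask(areas)
  schemes <- list()
  for (v in vars) {
    schemes[[v]] <- build_bin_scheme(grids[[v]], union, config$bin_widths[[v]])
  }
  log$n_bins <- vapply(schemes, function(s) s$n_bins, numeric(1))

  niche_summaries <- list()
  br <- list()
  for (v in vars) {
    codings <- list()
    for (sp in species) {
      so <- occ[occ$species == sp, , drop = FALSE]
      ov <- grid_values_at(grids[[v]], so$longitude, so$latitude)
      mv <- if (areas[[sp]]$status == "simulated") m_values(grids[[v]], areas[[sp]]) else NULL
      codings[[sp]] <- code_br(ov, mv, schemes[[v]])
      niche_summaries[[length(niche_summaries) + 1L]] <-
        niche_summary(ov, species = sp, variable = v, source = "occurrences")
      if (!is.null(mv)) {
        niche_summaries[[length(niche_summaries) + 1L]] <-
          niche_summary(mv, species = sp, variable = v, source = "M")
      }
    }
    br[[v]] <- build_br_matrix(codings, tree, schemes[[v]])
  }
  niche_summaries <- do.call(rbind, niche_summaries)

  ancestral <- list()
  for (v in vars) {
    ancestral[[v]] <- reconstruct_matrix(br[[v]], tree, theta = config$theta,
                                         lower = config$rate_bounds[1],
                                         upper = config$rate_bounds[2])
  }

  summary <- summarize_clade(tree, ancestral, br)
  log$n_changed <- stats::setNames(summary$clade$n_changed_strict,
                                   summary$clade$variable)

  projections <- list()
  labs <- node_labels(tree)
  for (v in vars) {
    for (i in seq_along(species)) {
      sp <- species[i]
      row <- summary$changes[summary$changes$species == sp &
                               summary$changes$variable == v, ]
      if (nrow(row) && row$has_change) {
        par <- tree$edge[tree$edge[, 2] == i, 1]
        projections[[paste(sp, v, sep = ".")]] <- suppressWarnings(
          project_change(areas[[sp]], grids[[v]], schemes[[v]],
                         ancestral[[v]]$state[labs[par], ], br[[v]][sp, ],
                         species = sp))
      }
    }
  }

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_pipeline_outputs(config$out_dir, occ, areas, schemes,
                                       br, ancestral, summary, projections,
                                       niche_summaries, frame, tree)
  }
  list(occurrences = occ, areas = areas, schemes = schemes, br = br,
       ancestral = ancestral, summary = summary, projections = projections,
       niche_summaries = niche_summaries, log = log, manifest = manifest)
}

write_pipeline_outputs <- function(out_dir, occ, areas, schemes, br,
                                   ancestral, summary, projections,
                                   niche_summaries, frame, tree) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(...) file.path(out_dir, paste0(...))
  write_occurrences(occ, p("occurrences_thinned.csv"))
  paths <- c(paths, p("occurrences_thinned.csv"))
  for (sp in names(areas)) {
    g <- env_grid(areas[[sp]]$mask + 0, variable = sp, xll = frame$xll,
                  yll = frame$yll, cellsize = frame$cellsize, nodata_value = -1)
    f <- p("M_", sp, ".asc")
    write_env_grid(g, f)
    paths <- c(paths, f)
  }
  status <- data.frame(species = names(areas),
                       status = vapply(areas, `[[`, character(1), "status"))
  utils::write.table(status, p("m_status.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  paths <- c(paths, p("m_status.tsv"))
  for (v in names(br)) {
    f <- p("br_", v, ".tsv"); write_br_matrix(br[[v]], f); paths <- c(paths, f)
    f1 <- p("ancestral_states_", v, ".tsv")
    f2 <- p("ancestral_prob_", v, ".tsv")
    write_ancestral_niche(ancestral[[v]], f1, f2)
    paths <- c(paths, f1, f2)
    es <- schemes[[v]]
    writeLines(sprintf("{\"variable\": \"%s\", \"width\": %.12g, \"global_min\": %.12g, \"global_max\": %.12g, \"edges\": [%s]}",
                       es$variable, es$width, es$global_min, es$global_max,
                       paste(sprintf("%.12g", es$edges), collapse = ", ")),
               p("bins_", v, ".json"))
    paths <- c(paths, p("bins_", v, ".json"))
  }
  write_dated_tree(tree, p("tree_annotated.nwk"))   # node labels = ASR row ids
  paths <- c(paths, p("tree_annotated.nwk"))
  utils::write.table(summary$changes, p("changes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(summary$clade, p("clade_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(niche_summaries, p("niche_summaries.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, p("changes.tsv"), p("clade_summary.tsv"), p("niche_summaries.tsv"))
  for (nm in names(projections)) {
    f <- p("projection_", nm, ".asc")
    export_category_grid(projections[[nm]], f)
    paths <- c(paths, f)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
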