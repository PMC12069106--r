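#' Specify a synthetic multi-source chemical universe
#'
#' A `universe_spec` pins down the joint membership structure of a synthetic
#' FCC universe: how many chemicals exist, how many are detected via
#' biomonitoring, listed in metabolome/exposome databases, or both, how the
#' step-1 detected set splits across the two FCC inventories, the step-2
#' prioritization outcome, hazard-tier quotas for the two hazard-mapped
#' subsets, and sample-type detection quotas for the evidence map.
#' [generate_universe()] then *constructs* memberships so that every quota
#' is satisfied exactly (free attributes are drawn from seeded uniform
#' choices); running the pipeline on the bundle recovers the quotas.
#'
#' All feasibility constraints are checked here, before anything is
#' generated; an infeasible combination is an immediate error.
#'
#' @param seed integer seed for the free (non-quota) attributes.
#' @param n_universe number of registry chemicals.
#' @param n_fccdb_only,n_migex_only,n_both partition of the step-1 detected
#'   set by inventory membership; must sum to
#'   `n_biomon_detected + n_metabolome_listed - n_overlap_biomon_metabolome`.
#' @param n_biomon_detected chemicals detected in >= 1 biomonitoring program.
#' @param n_biomon_monitored_only chemicals monitored but never detected in
#'   any program.
#' @param n_overlap_biomon_metabolome chemicals both biomonitoring-detected
#'   and metabolome-listed.
#' @param n_metabolome_listed chemicals listed in >= 1 metabolome/exposome
#'   database.
#' @param n_notdetected_in_metabolome how many of the monitored-but-never-
#'   detected chemicals are nevertheless metabolome-listed (and therefore
#'   end up in the `detected` category).
#' @param hmdb_status_counts named integer triple over [fcc_hmdb_statuses]:
#'   HMDB rows per metabolite status (distinct chemicals).
#' @param n_prioritized chemicals absent from all step-1 sources with enough
#'   FCCmigex detection entries.
#' @param prioritization_threshold minimum detection entries (default 5).
#' @param n_step2_with_studies,n_step2_all_negative of the prioritized set,
#'   how many have >= 1 eligible study, and how many of those have only
#'   negative records.
#' @param hazard_tier_quota `NULL`, or a list with named integer vectors
#'   `biomonitored` and `prioritized` over
#'   `c("high","medium","other_or_not_classified","no_hazard_data")`; the
#'   `prioritized` quota must sum to `n_prioritized`, the `biomonitored`
#'   quota defines (and must not exceed the feasible size of) the
#'   monitored-and-found-in-FCM subset.
#' @param n_prioritized_no_data_no_evidence `NULL`, or how many prioritized
#'   chemicals should lack both hazard data and any step-2 study.
#' @param sample_type_quota named integer vector over [fcc_sample_types]:
#'   distinct detected chemicals per sample type (multi-membership).
#' @param all_five_monitored,all_five_detected chemicals monitored in all
#'   five programs, and detected in all five.
#' @param metabolite_fraction fraction of biomonitoring detection rows
#'   routed through a metabolite analyte with a parent link (default 0.1),
#'   so metabolite-parent expansion is always exercised.
#' @param group_quota `NULL` (generic cycled labels), or a list with named
#'   integer vectors `biomonitored` and `prioritized` of group sizes.
#' @return a `universe_spec` object (validated list).
#' @seealso [fcchumon_marginals()], [generate_universe()]
#' @export
universe_spec <- function(seed = 1L,
                          n_universe,
                          n_fccdb_only = 0L, n_migex_only = 0L, n_both = 0L,
                          n_biomon_detected = 0L,
                          n_biomon_monitored_only = 0L,
                          n_overlap_biomon_metabolome = 0L,
                          n_metabolome_listed = 0L,
                          n_notdetected_in_metabolome = 0L,
                          hmdb_status_counts = c(detected_quantified = 0L,
                                                 detected_not_quantified = 0L,
                                                 expected_not_quantified = 0L),
                          n_prioritized = 0L,
                          prioritization_threshold = 5L,
                          n_step2_with_studies = 0L,
                          n_step2_all_negative = 0L,
                          hazard_tier_quota = NULL,
                          n_prioritized_no_data_no_evidence = NULL,
                          sample_type_quota = integer(0),
                          all_five_monitored = 0L,
                          all_five_detected = 0L,
                          metabolite_fraction = 0.1,
                          group_quota = NULL) {
  spec <- list(
    seed = as.integer(seed),
    n_universe = as.integer(n_universe),
    n_fccdb_only = as.integer(n_fccdb_only),
    n_migex_only = as.integer(n_migex_only),
    n_both = as.integer(n_both),
    n_biomon_detected = as.integer(n_biomon_detected),
    n_biomon_monitored_only = as.integer(n_biomon_monitored_only),
    n_overlap_biomon_metabolome = as.integer(n_overlap_biomon_metabolome),
    n_metabolome_listed = as.integer(n_metabolome_listed),
    n_notdetected_in_metabolome = as.integer(n_notdetected_in_metabolome),
    hmdb_status_counts = hmdb_status_counts,
    n_prioritized = as.integer(n_prioritized),
    prioritization_threshold = as.integer(prioritization_threshold),
    n_step2_with_studies = as.integer(n_step2_with_studies),
    n_step2_all_negative = as.integer(n_step2_all_negative),
    hazard_tier_quota = hazard_tier_quota,
    n_prioritized_no_data_no_evidence = n_prioritized_no_data_no_evidence,
    sample_type_quota = sample_type_quota,
    all_five_monitored = as.integer(all_five_monitored),
    all_five_detected = as.integer(all_five_detected),
    metabolite_fraction = metabolite_fraction,
    group_quota = group_quota
  )
  class(spec) <- "universe_spec"
  validate_universe_spec(spec)
  spec
}

#' @noRd
validate_universe_spec <- function(spec) {
  fail <- function(...) abort_fcc("Infeasible universe spec: ", ...)
  counts <- unlist(spec[c(
    "n_universe", "n_fccdb_only", "n_migex_only", "n_both",
    "n_biomon_detected", "n_biomon_monitored_only",
    "n_overlap_biomon_metabolome", "n_metabolome_listed",
    "n_notdetected_in_metabolome", "n_prioritized",
    "n_step2_with_studies", "n_step2_all_negative",
    "all_five_monitored", "all_five_detected"
  )])
  if (any(is.na(counts)) || any(counts < 0)) fail("counts must be non-negative")
  if (spec$prioritization_threshold < 1) fail("prioritization_threshold must be >= 1")
  if (spec$metabolite_fraction < 0 || spec$metabolite_fraction > 1) {
    fail("metabolite_fraction must be in [0, 1]")
  }
  if (spec$n_universe > 900000) fail("n_universe too large for the synthetic CAS range")

  n_det <- spec$n_biomon_detected + spec$n_metabolome_listed -
    spec$n_overlap_biomon_metabolome
  if (spec$n_overlap_biomon_metabolome >
        min(spec$n_biomon_detected, spec$n_metabolome_listed)) {
    fail("overlap exceeds a marginal")
  }
  part <- spec$n_fccdb_only + spec$n_migex_only + spec$n_both
  if (part != n_det) {
    fail(sprintf("inventory partition (%d) must sum to the detected total (%d)",
                 part, n_det))
  }
  if (spec$n_notdetected_in_metabolome > spec$n_biomon_monitored_only) {
    fail("n_notdetected_in_metabolome exceeds n_biomon_monitored_only")
  }
  if (spec$n_notdetected_in_metabolome >
        spec$n_metabolome_listed - spec$n_overlap_biomon_metabolome) {
    fail("not enough non-overlap metabolome slots for the monitored-only listings")
  }
  if (!identical(sort(names(spec$hmdb_status_counts)), sort(fcc_hmdb_statuses))) {
    fail("hmdb_status_counts must be named by the three HMDB statuses")
  }
  if (sum(spec$hmdb_status_counts) > spec$n_metabolome_listed) {
    fail("HMDB counts exceed the metabolome-listed total")
  }
  if (spec$all_five_detected > spec$all_five_monitored) {
    fail("all_five_detected exceeds all_five_monitored")
  }
  if (spec$all_five_monitored > spec$n_biomon_detected) {
    fail("all_five_monitored exceeds n_biomon_detected")
  }
  if (spec$n_step2_all_negative > spec$n_step2_with_studies ||
        spec$n_step2_with_studies > spec$n_prioritized) {
    fail("step-2 study counts must nest: all_negative <= with_studies <= prioritized")
  }
  n_mnd <- spec$n_biomon_monitored_only - spec$n_notdetected_in_metabolome
  if (n_det + n_mnd + spec$n_prioritized > spec$n_universe) {
    fail("universe too small for detected + monitored-only + prioritized")
  }

  if (!is.null(spec$hazard_tier_quota)) {
    bands <- c("high", "medium", "other_or_not_classified", "no_hazard_data")
    for (nm in c("biomonitored", "prioritized")) {
      q <- spec$hazard_tier_quota[[nm]]
      if (is.null(q) || !identical(sort(names(q)), sort(bands)) || any(q < 0)) {
        fail("hazard_tier_quota$", nm, " must be a non-negative vector over ",
             paste(bands, collapse = "/"))
      }
    }
    if (sum(spec$hazard_tier_quota$prioritized) != spec$n_prioritized) {
      fail("prioritized hazard quota must sum to n_prioritized")
    }
    n_sub <- sum(spec$hazard_tier_quota$biomonitored)
    monitored_det_cat <- spec$n_biomon_detected + spec$n_notdetected_in_metabolome
    eligible <- min(monitored_det_cat, spec$n_migex_only + spec$n_both) + n_mnd
    if (n_sub > eligible) {
      fail("biomonitored hazard subset larger than the monitored chemicals ",
           "that can carry FCCmigex detection entries")
    }
  }
  k <- spec$n_prioritized_no_data_no_evidence
  if (!is.null(k)) {
    if (is.null(spec$hazard_tier_quota)) fail("no-data placement needs hazard quotas")
    q_nodata <- spec$hazard_tier_quota$prioritized[["no_hazard_data"]]
    n_noev <- spec$n_prioritized - spec$n_step2_with_studies
    if (k > min(q_nodata, n_noev)) {
      fail("n_prioritized_no_data_no_evidence exceeds available chemicals")
    }
    if (q_nodata - k > spec$n_step2_with_studies) {
      fail("remaining no-data chemicals do not fit among those with studies")
    }
  }
  q <- spec$sample_type_quota
  if (length(q) > 0) {
    if (!all(names(q) %in% fcc_sample_types) || any(q < 0)) {
      fail("sample_type_quota must be named by valid sample types")
    }
    n_det2 <- spec$n_step2_with_studies - spec$n_step2_all_negative
    if (any(q > n_det2)) fail("a sample-type quota exceeds the detected step-2 set")
    if (n_det2 > 0 && sum(q) < n_det2) {
      fail("sample-type quotas cannot cover every detected step-2 chemical")
    }
    if (n_det2 == 0 && sum(q) > 0) fail("sample-type quotas without detected chemicals")
  }
  if (!is.null(spec$group_quota)) {
    for (nm in c("biomonitored", "prioritized")) {
      g <- spec$group_quota[[nm]]
      if (!is.null(g) && (is.null(names(g)) || any(g < 0))) {
        fail("group_quota$", nm, " must be a named non-negative vector")
      }
    }
    gp <- spec$group_quota$prioritized
    if (!is.null(gp) && sum(gp) > spec$n_prioritized) {
      fail("prioritized group quota exceeds n_prioritized")
    }
    gb <- spec$group_quota$biomonitored
    if (!is.null(gb) && !is.null(spec$hazard_tier_quota) &&
          sum(gb) > sum(spec$hazard_tier_quota$biomonitored)) {
      fail("biomonitored group quota exceeds the biomonitored subset")
    }
  }
  invisible(spec)
}

#' @export
print.universe_spec <- function(x, ...) {
  n_det <- x$n_biomon_detected + x$n_metabolome_listed -
    x$n_overlap_biomon_metabolome
  cat("<universe_spec>\n")
  cat(sprintf("  universe: %d chemicals (seed %d)\n", x$n_universe, x$seed))
  cat(sprintf("  step 1: %d detected (%d biomonitoring / %d metabolome / %d overlap), %d monitored-only\n",
              n_det, x$n_biomon_detected, x$n_metabolome_listed,
              x$n_overlap_biomon_metabolome, x$n_biomon_monitored_only))
  cat(sprintf("  step 2: %d prioritized (threshold %d), %d with studies, %d all-negative\n",
              x$n_prioritized, x$prioritization_threshold,
              x$n_step2_with_studies, x$n_step2_all_negative))
  invisible(x)
}

#' Marginal structure of the published FCChumon universe
#'
#' Preset [universe_spec()] reproducing the reported marginal counts of the
#' FCChumon resource: 14,402 known FCCs; a step-1 detected set of 3538
#' (194 biomonitoring-detected, 3528 metabolome-listed, 184 in both) split
#' 1883/863/792 across FCCdb-only/FCCmigex-only/both; 71 chemicals
#' monitored but never detected, of which 61 carry a metabolome listing
#' (leaving 10 monitored-not-detected after step 1); HMDB status counts
#' 367/1072/772; 175 prioritized chemicals at threshold 5, of which 68 have
#' eligible studies and 5 only negative ones; hazard-tier quotas
#' 100/44/77/14 for the 235-chemical biomonitored subset and 5/13/98/59 for
#' the prioritized subset (49 of the no-data chemicals also lacking any
#' step-2 study); sample-type quotas urine 28, serum 20, blood 13, plasma
#' 12, breast milk 13, umbilical cord 18, placenta 6; 13 chemicals
#' monitored in all five programs, 8 detected in all five.
#'
#' @param seed integer seed for the free attributes (quota recovery does not
#'   depend on it).
#' @return a `universe_spec`.
#' @export
fcchumon_marginals <- function(seed = 2024L) {
  universe_spec(
    seed = seed,
    n_universe = 14402L,
    n_fccdb_only = 1883L, n_migex_only = 863L, n_both = 792L,
    n_biomon_detected = 194L,
    n_biomon_monitored_only = 71L,
    n_overlap_biomon_metabolome = 184L,
    n_metabolome_listed = 3528L,
    n_notdetected_in_metabolome = 61L,
    hmdb_status_counts = c(detected_quantified = 367L,
                           detected_not_quantified = 1072L,
                           expected_not_quantified = 772L),
    n_prioritized = 175L,
    prioritization_threshold = 5L,
    n_step2_with_studies = 68L,
    n_step2_all_negative = 5L,
    hazard_tier_quota = list(
      biomonitored = c(high = 100L, medium = 44L,
                       other_or_not_classified = 77L, no_hazard_data = 14L),
      prioritized = c(high = 5L, medium = 13L,
                      other_or_not_classified = 98L, no_hazard_data = 59L)
    ),
    n_prioritized_no_data_no_evidence = 49L,
    sample_type_quota = c(urine = 28L, serum = 20L, blood = 13L, plasma = 12L,
                          breast_milk = 13L, umbilical_cord = 18L, placenta = 6L),
    all_five_monitored = 13L,
    all_five_detected = 8L,
    group_quota = list(
      biomonitored = c(VOCs = 51L, PFAS = 29L, pesticides = 25L, metals = 23L,
                       dioxin_like_compounds = 23L, flame_retardants = 20L,
                       phthalates_and_alternatives = 19L,
                       phenolic_compounds = 45L),
      prioritized = c(oligomers = 38L, antioxidants = 15L,
                      photoinitiators = 14L, plasticizers = 14L,
                      other_prioritized = 94L)
    )
  )
}

# synthetic identifiers: reserved high-numbered CAS range so generated
# numbers cannot collide with real registry numbers
synth_cas <- function(idx, base = 9000000L) {
  b1 <- base + as.integer(idx)
  b2 <- sprintf("%02d", (as.integer(idx) * 37L) %% 100L)
  chk <- mapply(cas_check_digit, b1, b2, USE.NAMES = FALSE)
  paste0(b1, "-", b2, "-", chk)
}

synth_inchikey <- function(idx) {
  enc <- vapply(as.integer(idx), function(i) {
    d <- integer(14)
    x <- i
    for (k in 14:1) {
      d[k] <- x %% 26L
      x <- x %/% 26L
    }
    paste(LETTERS[d + 1L], collapse = "")
  }, character(1))
  paste0(enc, "-", strrep("A", 10), "-N")
}

# distribute `quota` sample-type slots over n detected chemicals so that each
# chemical gets >= 1 type, each (chemical, type) pair occurs at most once, and
# each type's distinct-chemical count equals its quota exactly
assign_sample_slots <- function(n_fccs, quota) {
  quota <- quota[quota > 0]
  if (n_fccs == 0 || length(quota) == 0) {
    return(tibble::tibble(fcc = integer(), sample_type = character()))
  }
  quota <- quota[order(match(names(quota), fcc_sample_types))]
  slots <- rep(names(quota), quota)
  assigned <- vector("list", n_fccs)
  out_f <- integer(length(slots))
  out_t <- character(length(slots))
  k <- min(n_fccs, length(slots))
  for (j in seq_len(k)) {
    out_f[j] <- j
    out_t[j] <- slots[j]
    assigned[[j]] <- slots[j]
  }
  ptr <- 1L
  if (length(slots) > k) {
    for (m in (k + 1L):length(slots)) {
      s <- slots[m]
      j <- ptr
      for (step in 0:(n_fccs - 1L)) {
        j <- ((ptr - 1L + step) %% n_fccs) + 1L
        if (!(s %in% assigned[[j]])) break
      }
      assigned[[j]] <- c(assigned[[j]], s)
      out_f[m] <- j
      out_t[m] <- s
      ptr <- (j %% n_fccs) + 1L
    }
  }
  tibble::tibble(fcc = out_f, sample_type = out_t)
}

#' Generate a coherent synthetic source bundle from a universe spec
#'
#' Constructs the seven source tables (registry, biomonitoring analytes,
#' metabolome listings, FCCmigex entries, literature evidence records,
#' hazard records, group annotations) so that every quota in `spec` is
#' satisfied *exactly*. Identifiers are synthetic: CAS numbers from a
#' reserved high range (all check-digit valid, no collisions) and
#' format-valid synthetic InChIKeys for most non-mixture chemicals. A
#' fraction of biomonitoring detections is routed through metabolite rows
#' with parent links, and a fraction of metabolome rows matches via
#' InChIKey only, so both matching paths are always exercised.
#'
#' Generation is deterministic: the same spec (including its seed) yields a
#' byte-identical bundle. Randomness is confined to free attributes
#' (material/article labels, reference ids); the membership structure is
#' constructed, not sampled.
#'
#' @param spec a [universe_spec()].
#' @param dir optional directory: if supplied, each table is also written as
#'   `<kind>.csv` via [write_source()].
#' @return named list of tibbles: `registry`, `biomonitoring`, `metabolome`,
#'   `fccmigex`, `evidence_map`, `hazard`, `groups`.
#' @export
generate_universe <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "universe_spec"))
  validate_universe_spec(spec)
  withr::local_seed(spec$seed)

  n <- spec$n_universe
  nB <- spec$n_biomon_detected
  nL <- spec$n_notdetected_in_metabolome
  nD <- nB + spec$n_metabolome_listed - spec$n_overlap_biomon_metabolome
  nM <- spec$n_biomon_monitored_only - nL
  nP <- spec$n_prioritized
  thr <- spec$prioritization_threshold

  idx_B <- seq_len(nB)
  idx_L <- if (nL > 0) nB + seq_len(nL) else integer(0)
  idx_D <- seq_len(nD)
  idx_M <- if (nM > 0) nD + seq_len(nM) else integer(0)
  idx_P <- if (nP > 0) nD + nM + seq_len(nP) else integer(0)
  idx_R <- if (nD + nM + nP < n) (nD + nM + nP + 1L):n else integer(0)

  chem_id <- sprintf("FCC%06d", seq_len(n))
  cas <- synth_cas(seq_len(n))
  is_mixture <- seq_len(n) %% 400L == 0L
  has_ik <- seq_len(n) %% 3L != 0L & !is_mixture
  inchikey <- ifelse(has_ik, synth_inchikey(seq_len(n)), "")

  in_fccdb <- rep(TRUE, n)
  in_fccmigex <- rep(FALSE, n)
  if (nD > 0) {
    flags_D <- rep(c("both", "migex_only", "fccdb_only"),
                   c(spec$n_both, spec$n_migex_only, spec$n_fccdb_only))
    in_fccdb[idx_D] <- flags_D != "migex_only"
    in_fccmigex[idx_D] <- flags_D != "fccdb_only"
  }
  in_fccmigex[idx_M] <- TRUE
  in_fccmigex[idx_P] <- TRUE
  in_fccdb[idx_P] <- idx_P %% 2L == 0L

  registry <- tibble::tibble(
    chem_id = chem_id,
    cas = cas,
    inchikey = inchikey,
    smiles = "",
    names = paste0("synthetic chemical ", seq_len(n)),
    is_mixture = is_mixture,
    in_fccdb = in_fccdb,
    in_fccmigex = in_fccmigex
  )

  ## --- biomonitoring analytes -------------------------------------------
  bm_prog <- character(0)
  bm_chem <- integer(0)
  bm_status <- character(0)
  n_prog <- length(fcc_programs)
  for (b in idx_B) {
    if (b <= spec$all_five_detected) {
      bm_prog <- c(bm_prog, fcc_programs)
      bm_chem <- c(bm_chem, rep(b, n_prog))
      bm_status <- c(bm_status, rep("detected", n_prog))
    } else if (b <= spec$all_five_monitored) {
      bm_prog <- c(bm_prog, fcc_programs)
      bm_chem <- c(bm_chem, rep(b, n_prog))
      bm_status <- c(bm_status, c(rep("detected", n_prog - 1), "not_detected"))
    } else {
      bm_prog <- c(bm_prog, fcc_programs[(b %% n_prog) + 1L])
      bm_chem <- c(bm_chem, b)
      bm_status <- c(bm_status, "detected")
    }
  }
  for (i in c(idx_L, idx_M)) {
    bm_prog <- c(bm_prog, fcc_programs[(i %% n_prog) + 1L])
    bm_chem <- c(bm_chem, i)
    bm_status <- c(bm_status, "not_detected")
  }
  analyte_cas <- cas[bm_chem]
  parent_cas <- rep("", length(bm_chem))
  if (spec$metabolite_fraction > 0 && length(bm_chem) > 0) {
    every <- max(1L, as.integer(round(1 / spec$metabolite_fraction)))
    det_rows <- which(bm_status == "detected")
    routed <- det_rows[seq_along(det_rows) %% every == 0L]
    if (length(routed) > 0) {
      analyte_cas[routed] <- synth_cas(seq_along(routed), base = 8000000L)
      parent_cas[routed] <- cas[bm_chem[routed]]
    }
  }
  biomonitoring <- tibble::tibble(
    program = bm_prog,
    analyte_cas = analyte_cas,
    analyte_name = paste0("analyte ", analyte_cas),
    parent_cas = parent_cas,
    status = bm_status
  )

  ## --- metabolome listings ----------------------------------------------
  n_ov <- spec$n_overlap_biomon_metabolome
  met_idx <- c(
    if (n_ov > 0) seq_len(n_ov) else integer(0), # overlap with biomon-detected
    idx_L,                                       # monitored-only but listed
    if (nD > nB + nL) (nB + nL + 1L):nD else integer(0) # metabolome-only
  )
  n_hmdb <- sum(spec$hmdb_status_counts)
  hmdb_status <- rep(fcc_hmdb_statuses,
                     spec$hmdb_status_counts[fcc_hmdb_statuses])
  met_db <- c(rep("HMDB", n_hmdb), rep("BloodExposome", length(met_idx) - n_hmdb))
  met_status <- c(hmdb_status, rep("listed", length(met_idx) - n_hmdb))
  # a few chemicals additionally listed in Exposome Explorer (multi-db case)
  n_ee <- min(20L, length(met_idx))
  ee_idx <- met_idx[seq_len(n_ee)]
  met_all_idx <- c(met_idx, ee_idx)
  met_all_db <- c(met_db, rep("ExposomeExplorer", n_ee))
  met_all_status <- c(met_status, rep("listed", n_ee))
  met_cas <- cas[met_all_idx]
  met_ik <- inchikey[met_all_idx]
  # every 7th row with an InChIKey matches via InChIKey only
  ik_only <- seq_along(met_all_idx) %% 7L == 0L & met_ik != ""
  met_cas[ik_only] <- ""
  metabolome <- tibble::tibble(
    database = met_all_db,
    cas = met_cas,
    inchikey = met_ik,
    smiles = "",
    name = "",
    status = met_all_status
  )

  ## --- FCCmigex entries --------------------------------------------------
  n_sub <- if (!is.null(spec$hazard_tier_quota)) {
    sum(spec$hazard_tier_quota$biomonitored)
  } else {
    min(length(c(idx_B, idx_L)), spec$n_migex_only + spec$n_both) + nM
  }
  monitored_det_cat <- c(idx_B, idx_L)
  eligible <- c(monitored_det_cat[in_fccmigex[monitored_det_cat]], idx_M)
  sub_idx <- eligible[seq_len(min(n_sub, length(eligible)))]

  mg_chem <- integer(0)
  mg_detected <- logical(0)
  for (pos in seq_along(sub_idx)) {
    k <- 1L + (pos %% 3L)
    mg_chem <- c(mg_chem, rep(sub_idx[pos], k))
    mg_detected <- c(mg_detected, rep(TRUE, k))
  }
  for (pos in seq_along(idx_P)) {
    k <- thr + (pos %% 4L)
    mg_chem <- c(mg_chem, rep(idx_P[pos], k))
    mg_detected <- c(mg_detected, rep(TRUE, k))
  }
  # sub-threshold detection counts for a few chemicals outside all sources
  n_extra <- min(10L, length(idx_R))
  if (n_extra > 0 && thr > 1) {
    for (pos in seq_len(n_extra)) {
      k <- pos %% thr
      if (k > 0) {
        mg_chem <- c(mg_chem, rep(idx_R[pos], k))
        mg_detected <- c(mg_detected, rep(TRUE, k))
        in_fccmigex[idx_R[pos]] <- TRUE
      }
    }
  }
  # monitored-but-never-detected-in-FCM entries (excluded from counts)
  if (nM > 0) {
    mg_chem <- c(mg_chem, idx_M)
    mg_detected <- c(mg_detected, rep(FALSE, nM))
  }
  registry$in_fccmigex <- in_fccmigex
  n_mg <- length(mg_chem)
  fca_types <- c("packaging", "tableware", "processing equipment", "storage")
  fcm_materials <- c("plastic", "paper_board", "coated_metal", "glass", "silicone")
  fccmigex <- tibble::tibble(
    entry_id = sprintf("E%06d", seq_len(n_mg)),
    cas = cas[mg_chem],
    inchikey = "",
    smiles = "",
    name = "",
    fca_type = if (n_mg > 0) sample(fca_types, n_mg, replace = TRUE) else character(0),
    fcm_material = if (n_mg > 0) sample(fcm_materials, n_mg, replace = TRUE) else character(0),
    detected = mg_detected,
    reference_id = sprintf("REF%04d", (seq_len(n_mg) * 13L) %% 1000L)
  )

  ## --- step-2 evidence map ----------------------------------------------
  n_det2 <- spec$n_step2_with_studies - spec$n_step2_all_negative
  det2_idx <- idx_P[seq_len(n_det2)]
  neg2_idx <- if (spec$n_step2_all_negative > 0) {
    idx_P[n_det2 + seq_len(spec$n_step2_all_negative)]
  } else {
    integer(0)
  }
  slots <- assign_sample_slots(n_det2, spec$sample_type_quota)
  n_rec <- nrow(slots)
  ev <- tibble::tibble(
    study_id = sprintf("S%04d", seq_len(n_rec)),
    fcc_cas = cas[det2_idx[slots$fcc]],
    sample_type = slots$sample_type,
    method = as.character(ifelse(
      seq_len(n_rec) == 1L, "both",
      ifelse(seq_len(n_rec) %% 8L == 0L, "nontargeted", "targeted")
    )),
    analyte_form = as.character(ifelse(
      seq_len(n_rec) %% 11L == 0L, "specific_metabolite", "parent"
    )),
    detected = rep(TRUE, n_rec)
  )
  # the last two detected chemicals are identified only via an unspecific
  # shared metabolite
  if (n_det2 >= 2) {
    unspec <- ev$fcc_cas %in% cas[det2_idx[(n_det2 - 1L):n_det2]]
    ev$analyte_form[unspec] <- "unspecific_metabolite"
  }
  # a few extra negative records for detected chemicals (any-detection wins)
  extra <- list()
  nn <- min(5L, n_det2)
  if (nn > 0) {
    for (j in seq_len(nn)) {
      used <- slots$sample_type[slots$fcc == j]
      free <- setdiff(fcc_sample_types, used)
      if (length(free) == 0) next
      extra[[length(extra) + 1L]] <- tibble::tibble(
        study_id = sprintf("SN%03d", j),
        fcc_cas = cas[det2_idx[j]],
        sample_type = free[1],
        method = "targeted", analyte_form = "parent", detected = FALSE
      )
    }
  }
  for (j in seq_along(neg2_idx)) {
    extra[[length(extra) + 1L]] <- tibble::tibble(
      study_id = sprintf("SM%03d_%d", j, 1:2),
      fcc_cas = cas[neg2_idx[j]],
      sample_type = c("urine", "serum"),
      method = "targeted", analyte_form = "parent", detected = FALSE
    )
  }
  evidence_map <- dplyr::bind_rows(ev, extra)

  ## --- hazard records ----------------------------------------------------
  hz <- list()
  make_hazard_rows <- function(chem_pos, band, ordinal) {
    ca <- cas[chem_pos]
    src <- fcc_hazard_sources[(ordinal %% 2L) + 1L]
    cmr <- c("carcinogenicity", "mutagenicity", "reproductive_toxicity")
    if (band == "high") {
      tmpl <- list(c("carcinogenicity", "cat_1A"), c("mutagenicity", "cat_1B"),
                   c("reproductive_toxicity", "cat_1B"), c("stot_re", "cat_1"))
      pick <- tmpl[[(ordinal %% 4L) + 1L]]
      rows <- tibble::tibble(cas = ca, source = src, hazard_class = pick[1],
                             category = pick[2], has_data = TRUE)
      if (ordinal %% 10L == 0L) { # second inventory classifies lower
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          cas = ca, source = setdiff(fcc_hazard_sources, src),
          hazard_class = "carcinogenicity", category = "cat_2", has_data = TRUE
        ))
      }
      rows
    } else if (band == "medium") {
      cls <- c(cmr, "stot_re")[(ordinal %% 4L) + 1L]
      tibble::tibble(cas = ca, source = src, hazard_class = cls,
                     category = "cat_2", has_data = TRUE)
    } else if (band == "other_concern") {
      tibble::tibble(cas = ca, source = src, hazard_class = "other",
                     category = "other", has_data = TRUE)
    } else if (band == "not_classified") {
      cls <- fcc_hazard_classes[(ordinal %% 5L) + 1L]
      tibble::tibble(cas = ca, source = src, hazard_class = cls,
                     category = "none", has_data = TRUE)
    } else {
      NULL # no_hazard_data: absent from the inventories
    }
  }
  split_band <- function(band, size) {
    # the merged reporting band is stored with both internal tiers present
    if (band != "other_or_not_classified") return(rep(band, size))
    n_other <- ceiling(size / 2)
    rep(c("other_concern", "not_classified"), c(n_other, size - n_other))
  }
  if (!is.null(spec$hazard_tier_quota)) {
    q <- spec$hazard_tier_quota$biomonitored
    bands <- unlist(lapply(
      c("high", "medium", "other_or_not_classified", "no_hazard_data"),
      function(b) split_band(b, q[[b]])
    ))
    for (pos in seq_along(sub_idx)) {
      rows <- make_hazard_rows(sub_idx[pos], bands[pos], pos)
      if (!is.null(rows)) hz[[length(hz) + 1L]] <- rows
    }
    # prioritized subset: tier bands with controlled placement of the
    # no-data chemicals relative to step-2 study availability
    q2 <- spec$hazard_tier_quota$prioritized
    k49 <- spec$n_prioritized_no_data_no_evidence
    band2 <- rep(NA_character_, nP)
    if (!is.null(k49)) {
      n_nodata <- q2[["no_hazard_data"]]
      if (k49 > 0) band2[(nP - k49 + 1L):nP] <- "no_hazard_data"
      lead <- n_nodata - k49
      if (lead > 0) band2[seq_len(lead)] <- "no_hazard_data"
      rest <- unlist(lapply(c("high", "medium", "other_or_not_classified"),
                            function(b) split_band(b, q2[[b]])))
      band2[is.na(band2)] <- rest
    } else {
      band2 <- unlist(lapply(
        c("high", "medium", "other_or_not_classified", "no_hazard_data"),
        function(b) split_band(b, q2[[b]])
      ))
    }
    for (pos in seq_len(nP)) {
      rows <- make_hazard_rows(idx_P[pos], band2[pos], pos)
      if (!is.null(rows)) hz[[length(hz) + 1L]] <- rows
    }
  }
  hazard <- if (length(hz) > 0) {
    dplyr::bind_rows(hz)
  } else {
    tibble::tibble(cas = character(), source = character(),
                   hazard_class = character(), category = character(),
                   has_data = logical())
  }

  ## --- curated group annotations ----------------------------------------
  grp <- list()
  assign_groups <- function(member_idx, quota) {
    if (length(member_idx) == 0) return(NULL)
    if (is.null(quota)) {
      labels <- paste0("group_", LETTERS[1:5])[
        (seq_along(member_idx) %% 5L) + 1L
      ]
    } else {
      labels <- rep(names(quota), quota)
      labels <- labels[seq_len(min(length(labels), length(member_idx)))]
      member_idx <- member_idx[seq_along(labels)]
    }
    tibble::tibble(cas = cas[member_idx], group_label = labels)
  }
  grp[[1]] <- assign_groups(sub_idx, spec$group_quota$biomonitored)
  grp[[2]] <- assign_groups(idx_P, spec$group_quota$prioritized)
  groups <- dplyr::bind_rows(grp)
  if (nrow(groups) == 0) {
    groups <- tibble::tibble(cas = character(), group_label = character())
  }

  bundle <- list(
    registry = registry,
    biomonitoring = biomonitoring,
    metabolome = metabolome,
    fccmigex = fccmigex,
    evidence_map = evidence_map,
    hazard = hazard,
    groups = groups
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (kind in names(bundle)) {
      write_source(bundle[[kind]], file.path(dir, paste0(kind, ".csv")), kind)
    }
  }
  bundle
}
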