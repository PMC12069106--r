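# in-code fixture builders and independent oracles used across the suite

tiny_registry <- function(cas, inchikey = rep("", length(cas)),
                          smiles = rep("", length(cas)),
                          in_fccdb = rep(TRUE, length(cas)),
                          in_fccmigex = rep(FALSE, length(cas))) {
  chem_registry(tibble::tibble(
    chem_id = sprintf("C%03d", seq_along(cas)),
    cas = cas, inchikey = inchikey, smiles = smiles,
    names = paste0("chem ", seq_along(cas)),
    is_mixture = FALSE, in_fccdb = in_fccdb, in_fccmigex = in_fccmigex
  ))
}

biomon_row <- function(program, cas, status = "detected", parent = "") {
  tibble::tibble(program = program, analyte_cas = cas,
                 analyte_name = paste0("analyte ", cas),
                 parent_cas = parent, status = status)
}

metabolome_row <- function(db, cas, status = if (db == "HMDB")
                             "detected_quantified" else "listed",
                           inchikey = "", smiles = "") {
  tibble::tibble(database = db, cas = cas, inchikey = inchikey,
                 smiles = smiles, name = "", status = status)
}

hazard_row <- function(cas, class, category, source = "ECHA_CLP",
                       has_data = TRUE) {
  tibble::tibble(cas = cas, source = source, hazard_class = class,
                 category = category, has_data = has_data)
}

ev_row <- function(study, cas, sample_type = "urine", method = "targeted",
                   form = "parent", detected = TRUE) {
  tibble::tibble(study_id = study, fcc_cas = cas, sample_type = sample_type,
                 method = method, analyte_form = form, detected = detected)
}

# digit-loop CAS check oracle, independent of the implementation
cas_oracle_valid <- function(cas) {
  parts <- strsplit(cas, "-", fixed = TRUE)[[1]]
  digits <- as.integer(strsplit(paste0(parts[1], parts[2]), "")[[1]])
  total <- 0L
  pos <- 1L
  for (k in length(digits):1) {
    total <- total + digits[k] * pos
    pos <- pos + 1L
  }
  (total %% 10L) == as.integer(parts[3])
}

# brute-force step-1 resolution: nested loops over chemicals x source rows
oracle_step1 <- function(registry, analytes, listings) {
  out <- vector("list", nrow(registry))
  for (i in seq_len(nrow(registry))) {
    mon <- character(0)
    det <- character(0)
    listed <- character(0)
    for (j in seq_len(nrow(analytes))) {
      if (registry$cas[i] != "" && registry$cas[i] == analytes$analyte_cas[j]) {
        mon <- c(mon, analytes$program[j])
        if (analytes$status[j] == "detected") det <- c(det, analytes$program[j])
      }
    }
    for (j in seq_len(nrow(listings))) {
      hit <- (registry$cas[i] != "" && registry$cas[i] == listings$cas[j]) ||
        (registry$inchikey[i] != "" && registry$inchikey[i] == listings$inchikey[j]) ||
        (registry$smiles[i] != "" && registry$smiles[i] == listings$smiles[j])
      if (hit) listed <- c(listed, listings$database[j])
    }
    category <- if (length(det) > 0 || length(listed) > 0) {
      "detected"
    } else if (length(mon) > 0) {
      "monitored_not_detected"
    } else {
      "no_evidence"
    }
    out[[i]] <- tibble::tibble(
      chem_id = registry$chem_id[i], category = category,
      biomon_monitored_in = set_join(mon), biomon_detected_in = set_join(det),
      metabolome_listed_in = set_join(listed)
    )
  }
  dplyr::bind_rows(out)
}

# brute-force pairwise identifier matching over all left x right pairs
oracle_match_pairs <- function(left, right) {
  pairs <- list()
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      for (kind in c("cas", "inchikey", "smiles")) {
        lv <- if (kind %in% names(left)) left[[kind]][i] else ""
        rv <- if (kind %in% names(right)) right[[kind]][j] else ""
        if (!is.na(lv) && !is.na(rv) && lv != "" && lv == rv) {
          pairs[[length(pairs) + 1]] <- c(left$chem_id[i], as.character(j))
          break
        }
      }
    }
  }
  pairs
}

# random integer composition of n into k non-negative parts
rand_composition <- function(n, k) {
  if (k == 1) return(n)
  cuts <- sort(sample(0:n, k - 1, replace = TRUE))
  diff(c(0, cuts, n))
}

# sample an integer uniformly from lo..hi, tolerating empty ranges
rint <- function(lo, hi) if (hi <= lo) lo else sample(lo:hi, 1)

# a random feasible universe spec with small counts (fast to generate/run)
random_spec <- function(seed) {
  set.seed(seed)
  nb <- rint(3, 10)
  nmet <- rint(5, 20)
  ov <- rint(0, min(nb, nmet))
  ndet <- nb + nmet - ov
  part <- rand_composition(ndet, 3)
  mon_only <- rint(0, 5)
  ndm <- rint(0, min(mon_only, nmet - ov))
  hmdb <- rand_composition(rint(0, nmet), 3)
  npri <- rint(0, 6)
  nws <- rint(0, npri)
  nneg <- rint(0, nws)
  ndet2 <- nws - nneg
  stq <- if (ndet2 > 0) {
    c(urine = ndet2, serum = rint(0, ndet2))
  } else {
    integer(0)
  }
  a5m <- rint(0, min(2, nb))
  a5d <- rint(0, a5m)
  nmnd <- mon_only - ndm
  eligible <- min(nb + ndm, part[2] + part[3]) + nmnd
  nsub <- rint(0, eligible)
  universe_spec(
    seed = seed,
    n_universe = ndet + nmnd + npri + rint(2, 10),
    n_fccdb_only = part[1], n_migex_only = part[2], n_both = part[3],
    n_biomon_detected = nb,
    n_biomon_monitored_only = mon_only,
    n_overlap_biomon_metabolome = ov,
    n_metabolome_listed = nmet,
    n_notdetected_in_metabolome = ndm,
    hmdb_status_counts = c(detected_quantified = hmdb[1],
                           detected_not_quantified = hmdb[2],
                           expected_not_quantified = hmdb[3]),
    n_prioritized = npri,
    prioritization_threshold = rint(2, 5),
    n_step2_with_studies = nws,
    n_step2_all_negative = nneg,
    hazard_tier_quota = list(
      biomonitored = stats::setNames(rand_composition(nsub, 4),
        c("high", "medium", "other_or_not_classified", "no_hazard_data")),
      prioritized = stats::setNames(rand_composition(npri, 4),
        c("high", "medium", "other_or_not_classified", "no_hazard_data"))
    ),
    sample_type_quota = stq,
    all_five_monitored = a5m,
    all_five_detected = a5d
  )
}
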