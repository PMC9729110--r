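# Cohort analysis: mutation-catalog parsing, per-mutation impact calls from
# wild-type vs mutant minimum filter radii, closed-fraction summaries,
# validation against known gain/loss-of-function variants, and tumor-stage
# association with rank-sum statistics.

stage_levels <- c("I", "II", "III", "IV", "UNKNOWN")

#' Normalize free-text tumor-stage strings
#'
#' Collapses TNM sub-stages (`"Stage IIIA"` to `III`), accepts arabic 1-4,
#' and maps anything else (including missing) to `UNKNOWN`.
#'
#' @param stage Character vector.
#' @return Factor with levels I, II, III, IV, UNKNOWN.
#' @export
normalize_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("^([IV]+|[1-4]).*", "\\1", s)
  s[s == "1"] <- "I"; s[s == "2"] <- "II"; s[s == "3"] <- "III"; s[s == "4"] <- "IV"
  s[!(s %in% c("I", "II", "III", "IV"))] <- "UNKNOWN"
  s[is.na(stage)] <- "UNKNOWN"
  factor(s, levels = stage_levels)
}

parse_protein_change <- function(pc) {
  pc <- trimws(as.character(pc))
  m <- regmatches(pc, regexec("^(?:p\\.)?([A-Z])([0-9]+)([A-Z])$", pc,
                              perl = TRUE))
  tibble::tibble(
    wt = vapply(m, function(x) if (length(x) == 4L) x[2] else NA_character_, ""),
    position = vapply(m, function(x) if (length(x) == 4L) as.integer(x[3]) else NA_integer_, 1L),
    mut = vapply(m, function(x) if (length(x) == 4L) x[4] else NA_character_, "")
  )
}

#' Parse a mutation catalog table
#'
#' Reads a delimited table (CSV or TSV by extension, or a data frame) with
#' either a `protein_change` column in `p.R123C` style or explicit
#' `position`, `wt`, `mut` columns; optional `cancer_type`, `stage`,
#' `sample_id`. Synonymous and unparsable changes (nonsense, frameshift-style
#' strings, non-canonical letters) are skipped; skip counts are attached as
#' the `"skipped"` attribute and reported via a message.
#'
#' @param path File path or data frame.
#' @return Tibble of records: `position`, `wt`, `mut`, `cancer_type`,
#'   `stage` (normalized factor), `sample_id`, `protein_change`,
#'   `site_resolved` (`NA` until mapped onto a structure).
#' @export
parse_mutation_catalog <- function(path) {
  if (is.data.frame(path)) {
    tab <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) {
      abort(paste0("catalog not found: ", path), class = "porescreen_io_error")
    }
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
    tab <- tibble::as_tibble(read.table(path, header = TRUE, sep = sep,
                                        stringsAsFactors = FALSE,
                                        check.names = FALSE))
  }
  names(tab) <- tolower(names(tab))
  aa <- amino_acid_table()$code
  if ("protein_change" %in% names(tab)) {
    parsed <- parse_protein_change(tab$protein_change)
    pc <- as.character(tab$protein_change)
  } else if (all(c("position", "wt", "mut") %in% names(tab))) {
    parsed <- tibble::tibble(wt = toupper(as.character(tab$wt)),
                             position = as.integer(tab$position),
                             mut = toupper(as.character(tab$mut)))
    pc <- paste0("p.", parsed$wt, parsed$position, parsed$mut)
  } else {
    abort("catalog needs a protein_change column or position/wt/mut columns",
          class = "porescreen_schema_error")
  }
  unparsable <- is.na(parsed$wt) | is.na(parsed$position) | is.na(parsed$mut) |
    !(parsed$wt %in% aa) | !(parsed$mut %in% aa) |
    (!is.na(parsed$position) & parsed$position < 1L)
  synonymous <- !unparsable & parsed$wt == parsed$mut
  keep <- !unparsable & !synonymous
  out <- tibble::tibble(
    position = parsed$position[keep],
    wt = parsed$wt[keep],
    mut = parsed$mut[keep],
    cancer_type = if ("cancer_type" %in% names(tab)) {
      as.character(tab$cancer_type)[keep]
    } else NA_character_,
    stage = normalize_stage(if ("stage" %in% names(tab)) {
      tab$stage[keep]
    } else rep(NA_character_, sum(keep))),
    sample_id = if ("sample_id" %in% names(tab)) {
      as.character(tab$sample_id)[keep]
    } else NA_character_,
    protein_change = pc[keep],
    site_resolved = NA
  )
  skipped <- tibble::tibble(reason = c("unparsable", "synonymous"),
                            n = c(sum(unparsable), sum(synonymous)))
  if (sum(skipped$n) > 0L) {
    inform(sprintf("skipped %d unparsable and %d synonymous record(s)",
                   skipped$n[1], skipped$n[2]))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Map catalog positions onto structure residues
#'
#' Resolves each record's protein position to a residue key, requiring the
#' structure's residue name at that position to match the record's wild-type
#' amino acid. Records at positions absent from the structure (or with a
#' mismatching wild type) are flagged unresolved and excluded from radii
#' analyses downstream, but kept for catalog counts.
#'
#' @param structure A `channel_structure`.
#' @param records Catalog tibble from [parse_mutation_catalog()].
#' @param chains Chains to search, in order; default all chains.
#' @param offset Added to `position` to obtain the structure residue number
#'   (per-chain numbering offsets between transcript and model coordinates).
#' @return `records` with `chain`, `key` and `site_resolved` filled in.
#' @export
resolve_catalog_sites <- function(structure, records, chains = NULL, offset = 0L) {
  res <- structure_residues(structure)
  if (is.null(chains)) chains <- unique(res$chain)
  res <- res[res$chain %in% chains, ]
  res$wt1 <- aa_three_to_one(res$residue_name)
  key <- rep(NA_character_, nrow(records))
  chain <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- which(res$residue_number == records$position[i] + offset &
                   !is.na(res$wt1) & res$wt1 == records$wt[i])
    if (length(hit) > 0L) {
      key[i] <- res$key[hit[1]]
      chain[i] <- res$chain[hit[1]]
    }
  }
  records$chain <- chain
  records$key <- key
  records$site_resolved <- !is.na(key)
  n_un <- sum(!records$site_resolved)
  if (n_un > 0L) {
    inform(sprintf("%d of %d record(s) not resolved in the structure",
                   n_un, nrow(records)))
  }
  records
}

#' Classify pore impact from wild-type and mutant filter radii
#'
#' `close` if the mutant minimum filter radius falls more than `epsilon`
#' below the wild type, `open` if it rises more than `epsilon` above,
#' `neutral` otherwise. `epsilon = 0` reproduces a strict binary sign rule.
#'
#' @param wt_min_radius,mut_min_radius Radii in angstrom (vectorized).
#' @param epsilon Neutral half-band in angstrom; default 0.05.
#' @return Factor with levels close, neutral, open.
#' @export
classify_impact <- function(wt_min_radius, mut_min_radius, epsilon = 0.05) {
  if (epsilon < 0) abort("epsilon must be >= 0", class = "porescreen_input_error")
  if (any(wt_min_radius < 0, na.rm = TRUE) || any(mut_min_radius < 0, na.rm = TRUE)) {
    abort("radii must be non-negative", class = "porescreen_input_error")
  }
  delta <- mut_min_radius - wt_min_radius
  lab <- ifelse(delta < -epsilon, "close", ifelse(delta > epsilon, "open", "neutral"))
  factor(lab, levels = c("close", "neutral", "open"))
}

#' Per-mutation impact calls on a structure
#'
#' For each resolved record: introduce the mutation with
#' [mutate_residue()], recompute the pore profile across the selectivity
#' filter window, and compare minimum filter radii. The wild-type profile is
#' computed once; mutant profiles reuse the same stations, so deltas are not
#' confounded by alignment.
#'
#' @param structure A `channel_structure` with assigned radii.
#' @param records Catalog tibble; resolved with [resolve_catalog_sites()]
#'   first if it has no `key` column.
#' @param filter_residues Residue keys of the selectivity filter.
#' @param axis Channel axis (`NULL` for principal).
#' @param step,radius_cap,margin Profiling settings, see [compute_profile()]
#'   and [align_on_filter()].
#' @param epsilon Neutral band for [classify_impact()].
#' @param seed Integer seed for the profile searches.
#' @return Tibble of impact calls: the record columns plus `wt_min_radius`,
#'   `mut_min_radius`, `delta` and `label`. The wild-type minimum filter
#'   radius is attached as attribute `"wt_min_radius"`.
#' @export
compute_impact <- function(structure, records, filter_residues,
                           axis = NULL, step = 0.25, radius_cap = 15,
                           margin = 2, epsilon = 0.05, seed = 1) {
  if (is.null(axis) || identical(axis, "principal")) {
    axis <- principal_axis(structure)
  } else {
    axis <- normalize_axis(axis)
  }
  if (!"key" %in% names(records)) {
    records <- resolve_catalog_sites(structure, records)
  }
  win <- filter_z_window(structure, filter_residues, axis, margin)
  profile_window <- function(s, sd) {
    p <- compute_profile(s, axis = axis, z_range = win, step = step,
                         radius_cap = radius_cap, seed = sd)
    filter_window(p) <- win
    min_filter_radius(p)
  }
  wt_min <- profile_window(structure, seed)
  variants <- records |>
    dplyr::filter(.data$site_resolved) |>
    dplyr::distinct(.data$key, .data$wt, .data$mut)
  variants$mut_min_radius <- NA_real_
  for (i in seq_len(nrow(variants))) {
    mut_structure <- tryCatch(
      mutate_residue(structure, variants$key[i], variants$wt[i], variants$mut[i]),
      porescreen_unresolved_site = function(e) NULL,
      porescreen_identity_error = function(e) NULL
    )
    if (!is.null(mut_structure)) {
      variants$mut_min_radius[i] <- profile_window(mut_structure, seed)
    }
  }
  calls <- records |>
    dplyr::left_join(variants, by = c("key", "wt", "mut")) |>
    dplyr::mutate(
      site_resolved = .data$site_resolved & !is.na(.data$mut_min_radius),
      wt_min_radius = ifelse(.data$site_resolved, wt_min, NA_real_),
      delta = .data$mut_min_radius - .data$wt_min_radius,
      label = classify_impact(ifelse(is.na(.data$wt_min_radius), 0, .data$wt_min_radius),
                              ifelse(is.na(.data$mut_min_radius), 0, .data$mut_min_radius),
                              epsilon)
    )
  calls$label[!calls$site_resolved] <- NA
  attr(calls, "wt_min_radius") <- wt_min
  attr(calls, "epsilon") <- epsilon
  calls
}

#' Fraction of mutations predicted to close the channel
#'
#' @param calls Impact calls (tibble with `label`; rows with
#'   `site_resolved = FALSE` or missing labels are excluded).
#' @return One-row tibble: `n_close`, `n_neutral`, `n_open`, `n_total`,
#'   `fraction_closed`.
#' @export
summarize_closed_fraction <- function(calls) {
  if (nrow(calls) == 0L) {
    abort("no impact calls to summarize", class = "porescreen_input_error")
  }
  lab <- calls$label
  if ("site_resolved" %in% names(calls)) lab <- lab[calls$site_resolved %in% TRUE]
  lab <- lab[!is.na(lab)]
  if (length(lab) == 0L) {
    abort("no resolved impact calls to summarize",
          class = "porescreen_input_error")
  }
  tibble::tibble(
    n_close = sum(lab == "close"),
    n_neutral = sum(lab == "neutral"),
    n_open = sum(lab == "open"),
    n_total = length(lab),
    fraction_closed = sum(lab == "close") / length(lab)
  )
}

#' Validate impact calls against known gain/loss-of-function variants
#'
#' Gain-of-function variants are expected to be called `open`,
#' loss-of-function variants `close`. Annotations that match no call are
#' reported and excluded from the denominator.
#'
#' @param calls Impact calls tibble (with `position`, `wt`, `mut`, `label`).
#' @param known Tibble with `position`, `wt`, `mut` and `annotation`
#'   (`"GoF"` or `"LoF"`), or a path to such a CSV/TSV file.
#' @return List with `confusion` (tibble annotation x close/neutral/open),
#'   `concordance`, `n_annotated`, `n_unmatched`.
#' @export
validate_known_function <- function(calls, known) {
  if (is.character(known)) {
    sep <- if (grepl("\\.tsv$|\\.txt$", known, ignore.case = TRUE)) "\t" else ","
    known <- tibble::as_tibble(read.table(known, header = TRUE, sep = sep,
                                          stringsAsFactors = FALSE))
  }
  known <- tibble::as_tibble(known)
  names(known) <- tolower(names(known))
  stopifnot(all(c("position", "wt", "mut", "annotation") %in% names(known)))
  if (!all(known$annotation %in% c("GoF", "LoF"))) {
    abort("annotation must be 'GoF' or 'LoF'", class = "porescreen_input_error")
  }
  joined <- dplyr::inner_join(
    known,
    dplyr::distinct(calls, .data$position, .data$wt, .data$mut, .data$label),
    by = c("position", "wt", "mut")
  )
  joined <- joined[!is.na(joined$label), ]
  n_unmatched <- nrow(known) - nrow(joined)
  if (n_unmatched > 0L) {
    inform(sprintf("%d annotation(s) matched no resolved impact call", n_unmatched))
  }
  confusion <- joined |>
    dplyr::count(.data$annotation, .data$label) |>
    tidyr::pivot_wider(names_from = "label", values_from = "n",
                       values_fill = 0L)
  for (col in c("close", "neutral", "open")) {
    if (!col %in% names(confusion)) confusion[[col]] <- 0L
  }
  confusion <- confusion[, c("annotation", "close", "neutral", "open")]
  n_concordant <- sum(joined$annotation == "GoF" & joined$label == "open") +
    sum(joined$annotation == "LoF" & joined$label == "close")
  list(confusion = confusion,
       concordance = if (nrow(joined) > 0L) n_concordant / nrow(joined) else NA_real_,
       n_annotated = nrow(joined),
       n_unmatched = n_unmatched)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum comparison of two groups with midrank ties. Uses exact
#' enumeration of all group-label assignments when `n_a + n_b <= 16` and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction. The reported U is the statistic of group `a`.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return List: `U`, `p_two_tailed`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    abort("both groups must be nonempty", class = "porescreen_input_error")
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (n <= 16L && !ties) {
    idx_sets <- combn(n, n_a)
    rs <- rank(pooled)
    u_null <- apply(idx_sets, 2, function(ix) sum(rs[ix]) - n_a * (n_a + 1) / 2)
    p <- min(1, 2 * min(mean(u_null <= U + 1e-12), mean(u_null >= U - 1e-12)))
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    t_counts <- table(pooled)
    tie_term <- sum(t_counts^3 - t_counts) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      zc <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-zc))
    }
    method <- "normal_approx"
  }
  list(U = unname(U), p_two_tailed = unname(p), n_a = n_a, n_b = n_b,
       method = method)
}

#' Stage association of mutant filter radii
#'
#' Compares the distribution of mutant minimum filter radii between tumor
#' stages with two-tailed Mann-Whitney U tests: the reference stage against
#' each other populated stage (`pairs = "reference"`, the default) or every
#' pair (`pairs = "all"`). Medians are reported per group. Raw pairwise
#' p-values are the default; `adjust = "holm"` adds a Holm-adjusted column.
#'
#' @param calls Impact calls tibble with `stage` and `mut_min_radius`
#'   (records with stage UNKNOWN or unresolved sites are excluded).
#' @param reference Reference stage; default `"I"`.
#' @param pairs `"reference"` or `"all"`.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble: `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p_two_tailed`,
#'   `median_a`, `median_b` (and `p_adjusted` if requested).
#' @export
stage_association <- function(calls, reference = "I",
                              pairs = c("reference", "all"),
                              adjust = c("none", "holm")) {
  pairs <- match.arg(pairs)
  adjust <- match.arg(adjust)
  df <- calls
  if ("site_resolved" %in% names(df)) df <- df[df$site_resolved %in% TRUE, ]
  df <- df[!is.na(df$mut_min_radius) & !is.na(df$stage) & df$stage != "UNKNOWN", ]
  groups <- split(df$mut_min_radius, droplevels(factor(df$stage, levels = stage_levels)))
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (length(groups) < 2L) {
    abort("need at least two stages with >= 2 records each",
          class = "porescreen_input_error")
  }
  stages <- names(groups)
  cmp <- if (pairs == "reference") {
    if (!reference %in% stages) {
      abort(paste0("reference stage ", reference, " is not populated"),
            class = "porescreen_input_error")
    }
    tibble::tibble(group_a = reference, group_b = setdiff(stages, reference))
  } else {
    pr <- combn(stages, 2)
    tibble::tibble(group_a = pr[1, ], group_b = pr[2, ])
  }
  out <- purrr::pmap_dfr(cmp, function(group_a, group_b) {
    va <- groups[[group_a]]; vb <- groups[[group_b]]
    mw <- mann_whitney_u(va, vb)
    tibble::tibble(group_a = group_a, group_b = group_b,
                   n_a = mw$n_a, n_b = mw$n_b, U = mw$U,
                   p_two_tailed = mw$p_two_tailed,
                   median_a = median(va), median_b = median(vb))
  })
  if (adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_two_tailed, method = "holm")
  }
  out
}
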