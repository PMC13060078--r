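#' Element monoisotopic masses
#'
#' Monoisotopic masses (Da) of the elements the mass calculator understands,
#' with carbon defined as exactly 12.
#'
#' @return named numeric vector, element symbol -> Da.
#' @export
element_masses <- function() {
  c(C = 12.0, H = 1.00782503, N = 14.00307401, O = 15.99491462,
    S = 31.97207117, P = 30.97376200, Na = 22.98976928, Cl = 34.96885268)
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula formula string such as `"C6H8O6"` (element symbols with
#'   optional counts).
#' @return mass in Da. Masses are conventionally reported at 4 decimals:
#'   `monoisotopic_mass("C6H8O6")` prints as 176.0321, the neutral loss of a
#'   glucuronic-acid moiety.
#' @examples
#' round(monoisotopic_mass("C6H8O6"), 4)  # glucuronide neutral loss
#' round(monoisotopic_mass("H2O"), 4)
#' @export
monoisotopic_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!nzchar(formula)) stop("empty formula")
  masses <- element_masses()
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula))
    stop("malformed formula near: ", formula)
  total <- 0
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(masses)) stop("unknown element: ", el)
    total <- total + masses[[el]] * cnt
  }
  total
}

#' Drug-metabolite modification table
#'
#' Delta masses (Da) of phase-I/II biotransformations used for annotating
#' drug metabolites by their mass shift from the parent drug:
#' glucuronidation (+C6H8O6), hydroxylation (+O), demethylation (-CH2), and
#' their pairwise combinations. All deltas are computed from
#' [element_masses()], so each is reproducible from its composition change.
#'
#' @return data.frame with columns `name`, `composition` and `delta` (Da).
#' @export
modification_table <- function() {
  base <- data.frame(
    name = c("glucuronidation", "hydroxylation", "demethylation"),
    composition = c("+C6H8O6", "+O", "-CH2"),
    delta = c(monoisotopic_mass("C6H8O6"), monoisotopic_mass("O"),
              -monoisotopic_mass("CH2")),
    stringsAsFactors = FALSE
  )
  combos <- utils::combn(nrow(base), 2)
  comb <- data.frame(
    name = paste(base$name[combos[1, ]], base$name[combos[2, ]], sep = "+"),
    composition = paste0(base$composition[combos[1, ]],
                         base$composition[combos[2, ]]),
    delta = base$delta[combos[1, ]] + base$delta[combos[2, ]],
    stringsAsFactors = FALSE
  )
  # keep the conventional order: glucuronidation last in combo names
  comb$name <- sub("^(glucuronidation)\\+(.*)$", "\\2+\\1", comb$name)
  rbind(base, comb)
}

#' Neutral-loss query over a spectrum set
#'
#' A spectrum matches when some fragment sits at `precursor - loss` within
#' `tol` for at least one queried loss; all qualifying losses are reported.
#' The canonical use is hunting glucuronide conjugates via their
#' characteristic losses of 176.0321 and 194.0425 Da.
#'
#' @param spectra list of spectrum records (see [generate_spectra()] /
#'   [read_mgf()]).
#' @param losses numeric vector of neutral losses, Da (non-empty).
#' @param tol absolute m/z tolerance, Da.
#' @return data.frame of matches: spectrum_id, loss, fragment_mz,
#'   mass_error.
#' @export
neutral_loss_query <- function(spectra, losses, tol = 0.01) {
  if (length(losses) == 0) stop("`losses` must be non-empty")
  stopifnot(is.numeric(losses), tol >= 0)
  out <- list()
  for (sp in spectra) {
    for (loss in losses) {
      err <- sp$precursor_mz - sp$peaks[, "mz"] - loss
      hit <- which(abs(err) <= tol)
      if (length(hit)) {
        best <- hit[which.min(abs(err[hit]))]
        out[[length(out) + 1L]] <- data.frame(
          spectrum_id = sp$spectrum_id, loss = loss,
          fragment_mz = sp$peaks[best, "mz"], mass_error = err[best],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(spectrum_id = character(), loss = numeric(),
                      fragment_mz = numeric(), mass_error = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Shared-fragment query over a spectrum set
#'
#' A spectrum matches when at least `min_matched` of the queried fragment
#' m/z values each have a peak within `tol`. Matching is presence-based;
#' intensities are ignored except for an optional relative-intensity floor.
#' The canonical use is finding beta-blocker-related spectra via the four
#' shared aryloxypropanolamine backbone ions.
#'
#' @param spectra list of spectrum records.
#' @param fragments queried fragment m/z values (non-empty).
#' @param tol absolute m/z tolerance, Da.
#' @param min_matched minimum number of queried fragments that must be
#'   present (1..length(fragments)).
#' @param min_rel_intensity peaks below this fraction of the spectrum's base
#'   peak are ignored (default 0 = keep all).
#' @return data.frame: spectrum_id, precursor_mz, rt, n_matched,
#'   matched_fragments (semicolon-joined query values), max_mass_error.
#' @export
fragment_set_query <- function(spectra, fragments, tol = 0.01,
                               min_matched = 3, min_rel_intensity = 0) {
  if (length(fragments) == 0) stop("`fragments` must be non-empty")
  if (min_matched < 1 || min_matched > length(fragments))
    stop("`min_matched` must be in 1..", length(fragments))
  out <- list()
  for (sp in spectra) {
    pk <- sp$peaks
    if (min_rel_intensity > 0 && nrow(pk))
      pk <- pk[pk[, "intensity"] >= min_rel_intensity * max(pk[, "intensity"]),
               , drop = FALSE]
    errs <- vapply(fragments, function(f) {
      d <- abs(pk[, "mz"] - f)
      if (length(d)) min(d) else Inf
    }, numeric(1))
    hit <- errs <= tol
    if (sum(hit) >= min_matched) {
      out[[length(out) + 1L]] <- data.frame(
        spectrum_id = sp$spectrum_id, precursor_mz = sp$precursor_mz,
        rt = if (is.null(sp$rt)) NA_real_ else sp$rt,
        n_matched = sum(hit),
        matched_fragments = paste(format(fragments[hit], nsmall = 4),
                                  collapse = ";"),
        max_mass_error = max(errs[hit]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(spectrum_id = character(), precursor_mz = numeric(),
                      rt = numeric(), n_matched = integer(),
                      matched_fragments = character(),
                      max_mass_error = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# assign each match to the parent whose delta mass best matches a known
# modification; ties in best-modification error -> ambiguous (both listed)
assign_parent <- function(matches, parents, mods = modification_table(),
                          tol = 0.01) {
  best_err <- function(delta) {
    e <- abs(delta - mods$delta)
    min(e)
  }
  matches$parent <- NA_character_
  matches$delta <- NA_real_
  matches$parent_ambiguous <- FALSE
  for (i in seq_len(nrow(matches))) {
    deltas <- matches$precursor_mz[i] - parents$mz
    errs <- vapply(deltas, best_err, numeric(1))
    in_tol <- errs <= tol
    j <- if (any(in_tol)) which(in_tol)[which.min(errs[in_tol])]
         else which.min(abs(deltas))
    if (any(in_tol) && sum(abs(errs - errs[j]) <= 1e-9) > 1)
      matches$parent_ambiguous[i] <- TRUE
    matches$parent[i] <- parents$name[j]
    matches$delta[i] <- deltas[j]
  }
  matches
}

#' Co-occurrence filter for putative drug metabolites
#'
#' Retains a match only if the samples in which its spectrum occurs
#' intersect the samples in which its assigned parent drug occurs. Matches
#' with an empty occurrence set are flagged and not retained.
#'
#' @param matches data.frame from [fragment_set_query()] with a `parent`
#'   column (see [drug_metabolite_pipeline()]), or any data.frame with
#'   `spectrum_id` and `parent`.
#' @param spectra the spectrum set (source of per-spectrum sample
#'   occurrences).
#' @param parent_occurrences named list: parent name -> character vector of
#'   sample ids where that parent occurs.
#' @return `matches` with a logical `co_occurrence_ok` column.
#' @export
cooccurrence_filter <- function(matches, spectra, parent_occurrences) {
  occ <- lapply(spectra, function(s) s$samples)
  names(occ) <- vapply(spectra, function(s) s$spectrum_id, character(1))
  matches$co_occurrence_ok <- vapply(seq_len(nrow(matches)), function(i) {
    s <- occ[[matches$spectrum_id[i]]]
    p <- parent_occurrences[[matches$parent[i]]]
    length(s) > 0 && length(intersect(s, p)) > 0
  }, logical(1))
  matches
}

#' Retention-time precedence check
#'
#' Phase-I/II drug metabolites are more polar than their parent and elute
#' strictly earlier on reversed phase; equality fails the check. A missing
#' retention time yields `NA` (indeterminate), not failure.
#'
#' @param matches data.frame with `rt` and `parent` columns.
#' @param parent_rt named numeric: parent name -> retention time (minutes).
#' @return `matches` with a logical `rt_precedence_ok` column (NA when the
#'   metabolite RT is missing).
#' @export
rt_precedence_check <- function(matches, parent_rt) {
  matches$rt_precedence_ok <- ifelse(
    is.na(matches$rt), NA,
    matches$rt < parent_rt[matches$parent])
  matches
}

#' Delta-mass annotation of putative metabolites
#'
#' Annotates each match with the biotransformation whose delta mass
#' explains the precursor shift from the assigned parent within `tol`;
#' when no modification (or combination) fits, the match is labeled with
#' its bare delta mass. Multiple candidates within tolerance are all
#' reported, sorted by absolute mass error.
#'
#' @param matches data.frame with `delta` column (from parent assignment).
#' @param mods a [modification_table()].
#' @param tol absolute tolerance, Da.
#' @return `matches` with `annotation` and `annotation_error` columns.
#' @export
delta_mass_annotate <- function(matches, mods = modification_table(),
                                tol = 0.01) {
  ann <- character(nrow(matches))
  err <- rep(NA_real_, nrow(matches))
  for (i in seq_len(nrow(matches))) {
    e <- abs(matches$delta[i] - mods$delta)
    hit <- which(e <= tol)
    if (length(hit)) {
      hit <- hit[order(e[hit])]
      ann[i] <- paste(mods$name[hit], collapse = "|")
      err[i] <- e[hit[1]]
    } else {
      ann[i] <- sprintf("%+.4f", matches$delta[i])
    }
  }
  matches$annotation <- ann
  matches$annotation_error <- err
  matches
}

#' Composed drug-metabolite discovery pipeline
#'
#' Runs the full discovery chain on a spectrum set: shared-fragment query
#' for the backbone ions, parent assignment by best-explained delta mass,
#' co-occurrence filtering against the parent's samples, retention-time
#' precedence, and delta-mass annotation. Parent spectra themselves
#' (|delta| < 0.5 Da to a parent) are reported but flagged.
#'
#' @param spectra spectrum set.
#' @param parents data.frame: name, mz, rt (one row per parent drug).
#' @param parent_occurrences named list of parent sample occurrences.
#' @param fragments backbone fragment m/z values.
#' @param tol m/z tolerance, Da.
#' @param min_matched minimum backbone fragments required.
#' @param mods modification table.
#' @return annotated match data.frame with `is_parent`, `co_occurrence_ok`,
#'   `rt_precedence_ok`, `annotation` and `passes_all` columns.
#' @export
drug_metabolite_pipeline <- function(spectra, parents, parent_occurrences,
                                     fragments = backbone_fragments(),
                                     tol = 0.01, min_matched = 3,
                                     mods = modification_table()) {
  m <- fragment_set_query(spectra, fragments, tol = tol,
                          min_matched = min_matched)
  if (!nrow(m)) {
    m$parent <- character(0); m$passes_all <- logical(0)
    return(m)
  }
  m <- assign_parent(m, parents, mods = mods, tol = tol)
  m$is_parent <- abs(m$delta) < 0.5
  m <- cooccurrence_filter(m, spectra, parent_occurrences)
  m <- rt_precedence_check(m, stats::setNames(parents$rt, parents$name))
  m <- delta_mass_annotate(m, mods = mods, tol = tol)
  m$annotated <- is.finite(m$annotation_error)
  m$passes_all <- !m$is_parent & m$co_occurrence_ok &
    !is.na(m$rt_precedence_ok) & m$rt_precedence_ok & m$annotated
  m
}
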