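# Label-free molar quantification via the exponentially modified protein
# abundance index (emPAI): in silico tryptic digestion, observable-peptide
# counting within an instrument mass window, identification filtering, and
# compartment summaries.

# Monoisotopic residue masses (Da). Cys carries the fixed carbamidomethyl
# modification (+57.02146) to match the search settings under which the
# evidence is produced.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.02146, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259,
  M = 131.04049, H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
  W = 186.07931)
WATER_MONO <- 18.010565
PROTON_MONO <- 1.007276

check_sequence <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% names(AA_MONO))
  if (length(bad))
    stop_param("invalid residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' In silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is proline, and
#' returns the unique peptides with up to `missed_cleavages` internal missed
#' cleavage sites, in order of first appearance.
#'
#' @param sequence protein sequence over the 20 amino-acid letters.
#' @param missed_cleavages maximum missed cleavages (default 0).
#' @return Character vector of peptides.
#' @export
#' @examples
#' tryptic_digest("AKRPGKMR")              # "AK" "RPGK" "MR"
#' tryptic_digest("AKRPGKMR", 1)
tryptic_digest <- function(sequence, missed_cleavages = 0) {
  res <- check_sequence(sequence)
  if (missed_cleavages < 0) stop_param("'missed_cleavages' must be >= 0")
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment k spans (bounds[k], bounds[k+1]]
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (mc in 0:missed_cleavages) {
    for (i in seq_len(nfrag - mc)) {
      peps <- c(peps, paste(res[(bounds[i] + 1L):bounds[i + 1L + mc]],
                            collapse = ""))
    }
  }
  unique(peps)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water; cysteine is counted
#' carbamidomethylated.
#'
#' @param peptide peptide sequence.
#' @return Mass in Da.
#' @export
peptide_mass <- function(peptide) {
  res <- check_sequence(peptide)
  sum(AA_MONO[res]) + WATER_MONO
}

#' Default observable-peptide mass window
#'
#' Neutral monoisotopic mass bounds derived from an acquisition scan range of
#' m/z 375-1500 with precursor charge states 2-5:
#' lower = 375*2 - 2*m_H+, upper = 1500*5 - 5*m_H+.
#'
#' @return Numeric length-2 vector (Da).
#' @export
default_mass_window <- function() {
  c(375 * 2 - 2 * PROTON_MONO, 1500 * 5 - 5 * PROTON_MONO)
}

# Fully tryptic (0 missed cleavages) peptides inside the mass window.
observable_peptide_set <- function(sequence, mass_window = default_mass_window()) {
  peps <- tryptic_digest(sequence, 0)
  masses <- vapply(peps, peptide_mass, 0)
  peps[masses >= mass_window[1] & masses <= mass_window[2]]
}

#' Count observable tryptic peptides of a protein
#'
#' Number of fully tryptic peptides (no missed cleavages) whose monoisotopic
#' mass falls inside the instrument window; this is the emPAI denominator.
#'
#' @param sequence protein sequence.
#' @param mass_window numeric length-2 mass bounds in Da
#'   (default [default_mass_window()]).
#' @return Integer count (attribute `empty_digest` set if the digest itself
#'   is empty).
#' @export
observable_peptides <- function(sequence, mass_window = default_mass_window()) {
  peps <- tryptic_digest(sequence, 0)
  if (length(peps) == 0)
    return(structure(0L, empty_digest = TRUE))
  length(observable_peptide_set(sequence, mass_window))
}

#' Exponentially modified protein abundance index
#'
#' `empai = 10^(observed / observable) - 1`, proportional to protein molar
#' amount. `observed` above `observable` is capped with a warning.
#'
#' @param observed number of distinct observed peptides (>= 0).
#' @param observable number of observable tryptic peptides (>= 1).
#' @return emPAI value (>= 0).
#' @export
#' @examples
#' empai(4, 20)    # 10^0.2 - 1
empai <- function(observed, observable) {
  if (any(observable < 1)) stop_param("'observable' must be >= 1")
  if (any(observed < 0)) stop_param("'observed' must be >= 0")
  if (any(observed > observable)) {
    warning("observed > observable; capping at observable")
    observed <- pmin(observed, observable)
  }
  10^(observed / observable) - 1
}

#' Filter peptide-match evidence
#'
#' Applies the two identification filters used for label-free quantification:
#' matches with expect score above `expect_cutoff` are dropped, then proteins
#' lacking `min_peptides` distinct peptides are dropped. With
#' `scope = "any sample"` a protein is kept everywhere if *some* sample has
#' enough peptides (the rule used when comparing organ-specific abundances);
#' with `scope = "per sample"` the rule is applied within each sample.
#'
#' @param matches data.frame with columns `protein_id`, `peptide`, `expect`,
#'   `sample` (and any others, preserved).
#' @param expect_cutoff maximum retained expect score (default 0.05).
#' @param min_peptides minimum distinct peptides per protein (default 2).
#' @param scope `"any sample"` (default) or `"per sample"`.
#' @return List with `matches` (filtered data.frame) and `retention`
#'   (data.frame protein_id, n_peptides_max, retained).
#' @export
filter_identifications <- function(matches, expect_cutoff = 0.05,
                                   min_peptides = 2,
                                   scope = c("any sample", "per sample")) {
  scope <- match.arg(scope)
  if (is.null(matches) || nrow(matches) == 0)
    return(list(matches = matches,
                retention = data.frame(protein_id = character(0),
                                       n_peptides_max = integer(0),
                                       retained = logical(0))))
  keep <- matches$expect <= expect_cutoff
  m <- matches[keep, , drop = FALSE]
  if (nrow(m) == 0)
    return(list(matches = m,
                retention = data.frame(protein_id = unique(matches$protein_id),
                                       n_peptides_max = 0L, retained = FALSE)))
  counts <- stats::aggregate(peptide ~ protein_id + sample, data = m,
                             FUN = function(p) length(unique(p)))
  per_prot <- stats::aggregate(peptide ~ protein_id, data = counts, FUN = max)
  names(per_prot)[2] <- "n_peptides_max"
  per_prot$retained <- per_prot$n_peptides_max >= min_peptides
  if (scope == "any sample") {
    ok <- per_prot$protein_id[per_prot$retained]
    m <- m[m$protein_id %in% ok, , drop = FALSE]
  } else {
    key_ok <- with(counts[counts$peptide >= min_peptides, , drop = FALSE],
                   paste(protein_id, sample))
    m <- m[paste(m$protein_id, m$sample) %in% key_ok, , drop = FALSE]
  }
  rownames(m) <- NULL
  list(matches = m, retention = per_prot)
}

#' emPAI quantification of filtered evidence
#'
#' Counts distinct observed peptides per protein within each
#' sample (compartment x replicate) group and converts them to emPAI using
#' observable-peptide counts from the protein sequences.
#'
#' @param matches filtered evidence data.frame (`protein_id`, `peptide`,
#'   `sample`, `compartment`, `replicate`).
#' @param fasta named character vector of protein sequences.
#' @param mass_window observable-peptide window (Da).
#' @return data.frame: protein_id, sample, compartment, replicate, observed,
#'   observable, empai.
#' @export
empai_quantify <- function(matches, fasta,
                           mass_window = default_mass_window()) {
  if (nrow(matches) == 0)
    return(data.frame(protein_id = character(0), sample = character(0),
                      compartment = character(0), replicate = integer(0),
                      observed = integer(0), observable = integer(0),
                      empai = numeric(0)))
  missing <- setdiff(unique(matches$protein_id), names(fasta))
  if (length(missing))
    stop_param("sequences missing for: ", paste(missing, collapse = ", "))
  obs <- stats::aggregate(peptide ~ protein_id + sample + compartment + replicate,
                          data = matches,
                          FUN = function(p) length(unique(p)))
  names(obs)[names(obs) == "peptide"] <- "observed"
  observable <- vapply(names(fasta), function(id)
    as.integer(observable_peptides(fasta[[id]], mass_window)), 0L)
  obs$observable <- observable[obs$protein_id]
  if (any(obs$observable < 1))
    stop_param("protein with zero observable peptides cannot be quantified")
  obs$empai <- empai(obs$observed, obs$observable)
  obs[order(obs$compartment, obs$replicate, obs$protein_id), , drop = FALSE]
}

#' Molar percentages within replicate x compartment groups
#'
#' `mol% = 100 * empai / sum(empai)` within each group. Groups with zero
#' total are flagged and excluded.
#'
#' @param quants data.frame with `empai` and the grouping columns
#'   `compartment`, `replicate`.
#' @return Input with a `mol_percent` column; zero-sum groups removed (their
#'   keys are in attribute `dropped_groups`).
#' @export
molar_percentages <- function(quants) {
  key <- paste(quants$compartment, quants$replicate)
  totals <- tapply(quants$empai, key, sum)
  dropped <- names(totals)[totals <= 0]
  keep <- !(key %in% dropped)
  out <- quants[keep, , drop = FALSE]
  out$mol_percent <- 100 * out$empai / as.numeric(totals[paste(out$compartment,
                                                               out$replicate)])
  structure(out, dropped_groups = dropped)
}

#' Normalize replicates on equal total protein amount across organs
#'
#' Within each replicate, abundances are scaled so that the total summed
#' across all organs equals the across-replicate mean of those totals; after
#' normalization every replicate has the same cross-organ total.
#'
#' @param quants data.frame with columns `replicate`, `compartment` and a
#'   numeric abundance column.
#' @param organs character vector: every replicate must cover all of these.
#' @param value name of the abundance column (default `"empai"`).
#' @return `quants` with the abundance column rescaled.
#' @export
normalize_replicates <- function(quants, organs = unique(quants$compartment),
                                 value = "empai") {
  reps <- unique(quants$replicate)
  for (r in reps) {
    have <- unique(quants$compartment[quants$replicate == r])
    miss <- setdiff(organs, have)
    if (length(miss))
      stop_param("replicate ", r, " missing organ(s): ",
                 paste(miss, collapse = ", "))
  }
  sel <- quants$compartment %in% organs
  totals <- tapply(quants[[value]][sel], quants$replicate[sel], sum)
  target <- mean(totals)
  scale <- target / totals[as.character(quants$replicate)]
  quants[[value]] <- quants[[value]] * as.numeric(scale)
  quants
}

#' GH-family shares and compartment contrasts
#'
#' Renormalizes molar percentages within the glycosyl-hydrolase subset to
#' give per-family shares (per replicate and averaged), and reports the
#' hemocyanin compartment contrast (mean +/- SD of mol% per compartment).
#'
#' @param quants output of [molar_percentages()] (needs `mol_percent`).
#' @param annotations named character vector protein_id -> family (GH family
#'   label such as `"GH7"`, or `"hemocyanin"`, `"ferritin"`, `"other"`);
#'   proteins not covered are treated as `"other"`.
#' @return List with `gh_shares` (family, compartment, replicate,
#'   share_percent), `gh_shares_mean` (family, compartment, mean share),
#'   `hemocyanin` (compartment, mean, sd, n), and `empty` flag when no GH
#'   protein is present.
#' @export
family_summary <- function(quants, annotations) {
  fam <- annotations[quants$protein_id]
  fam[is.na(fam)] <- "other"
  quants$family <- as.character(fam)
  is_gh <- grepl("^GH", quants$family)
  out <- list(empty = !any(is_gh))
  if (any(is_gh)) {
    gh <- quants[is_gh, , drop = FALSE]
    tot <- stats::aggregate(mol_percent ~ compartment + replicate, gh, sum)
    names(tot)[3] <- "gh_total"
    byfam <- stats::aggregate(mol_percent ~ family + compartment + replicate,
                              gh, sum)
    byfam <- merge(byfam, tot, by = c("compartment", "replicate"))
    byfam$share_percent <- 100 * byfam$mol_percent / byfam$gh_total
    out$gh_shares <- byfam[order(byfam$compartment, byfam$replicate,
                                 byfam$family),
                           c("family", "compartment", "replicate",
                             "share_percent")]
    out$gh_shares_mean <- stats::aggregate(share_percent ~ family + compartment,
                                           byfam, mean)
  }
  hc <- quants[quants$family == "hemocyanin", , drop = FALSE]
  if (nrow(hc)) {
    per_rep <- stats::aggregate(mol_percent ~ compartment + replicate, hc, sum)
    out$hemocyanin <- do.call(rbind, lapply(split(per_rep, per_rep$compartment),
      function(d) data.frame(compartment = d$compartment[1],
                             mean = mean(d$mol_percent),
                             sd = stats::sd(d$mol_percent),
                             n = nrow(d))))
    rownames(out$hemocyanin) <- NULL
  }
  out
}

#' Protein family annotations of a proteome preset
#'
#' @param preset a [proteome_preset()].
#' @return Named character vector protein_id -> family.
#' @export
preset_annotations <- function(preset) {
  stats::setNames(as.character(preset$proteins$family),
                  as.character(preset$proteins$protein_id))
}
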