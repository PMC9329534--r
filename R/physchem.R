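# Insert and protein physicochemistry: additive masses, isoelectric points,
# Wimley-White octanol hydrophobicity, extinction coefficients, and
# construction of loop-insertion variants.

#' Mass added by a peptide insert
#'
#' Sum of average residue masses over the insert sequence, times the repeat
#' count. No water term is included: this is the mass *added* when the peptide
#' is inserted into a protein chain, so it is exactly linear in `repeats`.
#'
#' @param sequence One-letter peptide string (standard residues only).
#' @param repeats Positive integer number of tandem copies (default 1).
#' @return Mass in Da.
#' @examples
#' insert_mass("SPLAT")            # 469.54
#' insert_mass("AGPGA", repeats = 4)
#' @export
insert_mass <- function(sequence, repeats = 1L) {
  check_repeats(repeats)
  res <- split_residues(sequence)
  repeats * sum(.aa_mass[res])
}

#' Wimley-White octanol hydrophobicity of a peptide insert
#'
#' Additive sum of the Wimley-White whole-residue water-to-octanol transfer
#' free energies, times the repeat count. Positive values disfavour the
#' hydrophobic (octanol) phase.
#'
#' @inheritParams insert_mass
#' @return Transfer free energy in kcal/mol.
#' @examples
#' ww_octanol("SPLAT")             # +0.10 kcal/mol
#' ww_octanol("AGPGA", repeats = 2) # +6.88 kcal/mol
#' @export
ww_octanol <- function(sequence, repeats = 1L) {
  check_repeats(repeats)
  res <- split_residues(sequence)
  repeats * sum(.ww_octanol_scale[res])
}

#' Net charge of a free peptide at a given pH
#'
#' Henderson-Hasselbalch net charge with a free N-terminal amine (pKa
#' specific to the first residue), a free C-terminal carboxyl (pKa 3.55), and
#' all ionizable side chains. Positive groups contribute
#' \eqn{1/(1+10^{pH-pKa})}; negative groups contribute
#' \eqn{-1/(1+10^{pKa-pH})}. The function is strictly decreasing in pH, so
#' its root (the isoelectric point) is unique.
#'
#' @param sequence One-letter peptide string.
#' @param pH Numeric vector of pH values.
#' @return Net charge (elementary charges), vectorized over `pH`.
#' @examples
#' peptide_charge("SPLAT", c(3, 5.24, 8))
#' @export
peptide_charge <- function(sequence, pH) {
  res <- split_residues(sequence)
  pos_pka <- c(.pka_nterm[res[1]],
               .pka_side[res][.pka_side_sign[res] > 0])
  neg_pka <- c(.pka_cterm,
               .pka_side[res][.pka_side_sign[res] < 0])
  pos_pka <- pos_pka[!is.na(pos_pka)]
  neg_pka <- neg_pka[!is.na(neg_pka)]
  vapply(pH, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point of a free peptide
#'
#' Solves net charge = 0 by bisection on [0, 14]. Because the net-charge
#' function is strictly decreasing in pH the root is unique; iteration stops
#' when |charge| < 1e-4 or the bracketing interval is narrower than 0.005 pH.
#'
#' @param sequence One-letter peptide string.
#' @return pH at which the peptide carries zero net charge.
#' @examples
#' isoelectric_point("SPLAT") # 5.24
#' isoelectric_point("AGPGA") # 5.57
#' @export
isoelectric_point <- function(sequence) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- peptide_charge(sequence, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 0.005) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Molar extinction coefficient at 280 nm
#'
#' ProtParam rule: 5500 per tryptophan + 1490 per tyrosine + 125 per cystine
#' (disulfide-bonded cysteine pair). Free cysteines do not absorb; the
#' cystine count defaults to 0.
#'
#' @param sequence One-letter protein string.
#' @param n_cystine Number of disulfide bonds assumed present (default 0).
#' @return Extinction coefficient in M^-1 cm^-1.
#' @examples
#' extinction_coefficient("WY") # 6990
#' extinction_coefficient(ompx_mature()) # 34840
#' @export
extinction_coefficient <- function(sequence, n_cystine = 0L) {
  res <- split_residues(sequence)
  5500L * sum(res == "W") + 1490L * sum(res == "Y") + 125L * n_cystine
}

#' Physicochemical property table for a set of peptide inserts
#'
#' Data-frame-in, tibble-out: for each (insert sequence, repeat count) row,
#' computes the added mass, the isoelectric point of the free peptide (of the
#' concatemer, though pI is invariant under concatemerization when no side
#' chain ionizes), and the additive Wimley-White octanol hydrophobicity.
#'
#' @param inserts Data frame with columns `insert` (one-letter sequence) and
#'   `repeats` (positive integer).
#' @param digits Rounding for the report columns (default 2, the package's
#'   reporting convention); use `NULL` for full precision.
#' @return The input tibble with columns `mass_da`, `pi`,
#'   `ww_octanol_kcal_mol` appended.
#' @examples
#' insert_properties(tibble::tibble(
#'   insert = c("SPLAT", "AGPGA"), repeats = c(1, 4)
#' ))
#' @export
insert_properties <- function(inserts, digits = 2) {
  stopifnot(is.data.frame(inserts), all(c("insert", "repeats") %in% names(inserts)))
  out <- inserts %>%
    dplyr::mutate(
      mass_da = purrr::map2_dbl(.data$insert, .data$repeats, insert_mass),
      pi = purrr::map2_dbl(.data$insert, .data$repeats, function(s, r) {
        isoelectric_point(strrep(s, r))
      }),
      ww_octanol_kcal_mol = purrr::map2_dbl(.data$insert, .data$repeats, ww_octanol)
    ) %>%
    tibble::as_tibble()
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("mass_da", "pi", "ww_octanol_kcal_mol"), ~ round(.x, digits)
    ))
  }
  out
}

# Loop spans of mature OmpX (1-based residue indices).
.loop_spans <- list(`2` = 49:59, `3` = 91:103)

check_repeats <- function(repeats) {
  if (!is.numeric(repeats) || length(repeats) != 1L || is.na(repeats) ||
      repeats < 1 || repeats != round(repeats)) {
    abort("`repeats` must be a single positive integer.")
  }
}

#' Build a loop-insertion construct sequence
#'
#' Inserts tandem peptide repeats into extracellular loop 2 (residues 49-59)
#' and/or loop 3 (residues 91-103) of a mature barrel sequence. Each insert
#' block is placed after the midpoint residue of its loop span (after residue
#' 54 for loop 2, after residue 97 for loop 3, in base-sequence numbering),
#' keeping both flanking loop halves intact. At most one insert block per
#' loop.
#'
#' @param base One-letter mature protein sequence (default the packaged
#'   mature OmpX sequence).
#' @param inserts Data frame with columns `loop` (2 or 3), `insert`
#'   (one-letter peptide) and `repeats`; zero rows returns the base sequence
#'   unchanged.
#' @return The construct sequence as a character scalar, with attribute
#'   `loop_spans`: a list giving the residue indices of each loop (original
#'   span plus any inserted residues) in construct numbering.
#' @examples
#' wt <- build_construct(inserts = NULL)
#' v  <- build_construct(inserts = tibble::tibble(
#'   loop = 3, insert = "AGPGA", repeats = 1
#' ))
#' nchar(v) - nchar(wt) # 5
#' @export
build_construct <- function(base = ompx_mature(), inserts = NULL) {
  res <- split_residues(base, arg = "base")
  n <- length(res)
  if (max(.loop_spans$`3`) > n) {
    abort("`base` is shorter than the loop-3 span (residues 91-103).")
  }
  spans <- list(`2` = .loop_spans$`2`, `3` = .loop_spans$`3`)
  if (is.null(inserts) || nrow(inserts) == 0L) {
    out <- paste(res, collapse = "")
    attr(out, "loop_spans") <- spans
    return(out)
  }
  stopifnot(is.data.frame(inserts),
            all(c("loop", "insert", "repeats") %in% names(inserts)))
  if (!all(inserts$loop %in% c(2, 3))) {
    abort("`loop` must be 2 or 3.")
  }
  if (anyDuplicated(inserts$loop)) {
    abort("At most one insert block per loop.")
  }
  # Insert the higher-position loop first so earlier indices stay valid.
  ins <- inserts[order(inserts$loop, decreasing = TRUE), , drop = FALSE]
  midpoint <- c(`2` = 54L, `3` = 97L)
  shift <- c(`2` = 0L, `3` = 0L)
  for (i in seq_len(nrow(ins))) {
    check_repeats(ins$repeats[i])
    loop <- as.character(ins$loop[i])
    block <- split_residues(strrep(ins$insert[i], ins$repeats[i]),
                            arg = "insert")
    pos <- midpoint[loop]
    res <- append(res, block, after = pos)
    len <- length(block)
    # Construct-numbering spans: this loop widens; loop 3 shifts if loop 2
    # received an insert (handled because loop 2 is processed last).
    spans[[loop]] <- seq.int(min(spans[[loop]]), max(spans[[loop]]) + len)
    if (loop == "2" && !is.null(spans$`3`)) {
      spans$`3` <- spans$`3` + as.integer(len)
    }
    shift[loop] <- len
  }
  out <- paste(res, collapse = "")
  attr(out, "loop_spans") <- spans
  out
}

#' Mature OmpX sequence
#'
#' The mature chain of E. coli OmpX (UniProt P0A917, 148 residues after
#' signal-peptide cleavage), shipped as a FASTA fixture. Its composition
#' (2 Trp, 16 Tyr, no Cys) gives a ProtParam extinction coefficient of
#' 34,840 M^-1 cm^-1.
#'
#' @return One-letter sequence string.
#' @export
ompx_mature <- function() {
  path <- system.file("extdata", "ompx_mature.fasta", package = "loopfold",
                      mustWork = TRUE)
  unname(read_fasta(path)[1])
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings for protein FASTA I/O, returning and
#' accepting named character vectors of one-letter sequences.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()`: named character vector. `write_fasta()`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences))
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}
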