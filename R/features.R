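PHYSCHEM_SCALES <- c(paste0("kf", 1:10), "strength", "mjenergy",
                     "core", "rim", "volume", "polarity", "disorder",
                     "surface", "alpha", "beta", "turn", "charge",
                     "hydropathy")

FEATURE_NAMES <- c(paste0("kf", 1:10), "strength", "mjenergy",
                   "cdr3_length", "ndn_length", "n_insertions",
                   "vdins", "djins",
                   "core", "rim", "volume", "polarity", "disorder",
                   "surface", "alpha", "beta", "turn", "charge",
                   "hydropathy")

#' V(D)J junction insertion statistics
#'
#' Computes, from the 0-based junction markers of each clonotype:
#' * `ndn_length = j_start - v_end - 1`, the whole inter-V-J stretch;
#' * `vdins = max(0, d_start - v_end - 1)` and
#'   `djins = max(0, j_start - d_end - 1)`, the non-templated (N)
#'   additions at the V-D and D-J junctions (clamped at 0 when exonuclease
#'   chewback makes the segments overlap);
#' * `n_insertions = vdins + djins`, or `ndn_length` when no D segment was
#'   identified (in which case `vdins`/`djins` are `NA`).
#'
#' Clonotypes without defined `v_end`/`j_start` yield `NA` throughout.
#'
#' @param rep a [repertoire()] (or data.frame with marker columns)
#' @return data.frame with columns `ndn_length`, `n_insertions`, `vdins`,
#'   `djins`, one row per clonotype
#' @export
junction_insertions <- function(rep) {
  v_end <- rep$v_end; d_start <- rep$d_start
  d_end <- rep$d_end; j_start <- rep$j_start
  ntlen <- nchar(rep$cdr3nt)
  vj <- v_end >= 0L & j_start >= 0L
  if (any(vj & (v_end >= ntlen | j_start >= ntlen)))
    stop("junction marker beyond cdr3nt length")
  ndn <- ifelse(vj, j_start - v_end - 1L, NA_integer_)
  ddef <- vj & d_start >= 0L & d_end >= 0L
  vdins <- ifelse(ddef, pmax(0L, d_start - v_end - 1L), NA_integer_)
  djins <- ifelse(ddef, pmax(0L, j_start - d_end - 1L), NA_integer_)
  nins <- ifelse(ddef, vdins + djins, ndn)
  data.frame(ndn_length = ndn, n_insertions = nins,
             vdins = vdins, djins = djins)
}

#' CDR3 length
#' @param rep a [repertoire()]
#' @param unit `"nt"` or `"aa"`
#' @return integer vector of lengths
#' @export
cdr3_length <- function(rep, unit = c("nt", "aa")) {
  unit <- match.arg(unit)
  nchar(if (unit == "nt") rep$cdr3nt else rep$cdr3aa)
}

weighted_mean_narm <- function(x, w) {
  ok <- !is.na(x)
  if (!any(ok)) return(NA_real_)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

#' The 28-parameter repertoire feature vector
#'
#' Computes the standard per-cloneset summary used for multivariate
#' repertoire comparison: the ten Kidera factors, interaction `strength`,
#' `mjenergy`, CDR3 length (nucleotides), NDN length, total N insertions,
#' `vdins`, `djins`, and the `core`, `rim`, `volume`, `polarity`,
#' `disorder`, `surface`, `alpha`, `beta`, `turn`, `charge` and
#' `hydropathy` scales — 28 parameters in all. Physicochemical scales are
#' scored on the CDR3 middle region ([clonotype_property()]); every
#' parameter is averaged over clonotypes, weighted by clonotype frequency
#' unless `weighted = FALSE`. Insertion parameters average over the
#' clonotypes for which they are defined (weights renormalized).
#'
#' @param rep a nonempty [repertoire()]
#' @param table property table, default [aa_property_table()]
#' @param weighted weight by clonotype frequency? Default TRUE.
#' @param k middle-region length, default 5
#' @return named numeric vector of length 28
#' @export
feature_vector <- function(rep, table = aa_property_table(),
                           weighted = TRUE, k = 5L) {
  if (!nrow(rep)) stop("empty repertoire")
  w <- if (weighted) rep$count / sum(rep$count)
       else rep(1 / nrow(rep), nrow(rep))
  ji <- junction_insertions(rep)
  out <- c(
    vapply(PHYSCHEM_SCALES, function(s)
      weighted_mean_narm(clonotype_property(rep$cdr3aa, s, table, k), w),
      numeric(1)),
    cdr3_length = weighted_mean_narm(cdr3_length(rep, "nt"), w),
    ndn_length = weighted_mean_narm(ji$ndn_length, w),
    n_insertions = weighted_mean_narm(ji$n_insertions, w),
    vdins = weighted_mean_narm(ji$vdins, w),
    djins = weighted_mean_narm(ji$djins, w))
  out[FEATURE_NAMES]
}

#' Feature matrix for a set of repertoires
#'
#' Applies [feature_vector()] to each repertoire and binds the results
#' with donor/subset/chain metadata columns, one row per repertoire.
#'
#' @param reps list of [repertoire()] objects
#' @inheritParams feature_vector
#' @return data.frame: `donor_id`, `subset`, `chain`, then 28 feature
#'   columns
#' @export
feature_matrix <- function(reps, table = aa_property_table(),
                           weighted = TRUE, k = 5L) {
  rows <- lapply(reps, function(r) {
    fv <- feature_vector(r, table, weighted, k)
    cbind(data.frame(donor_id = attr(r, "donor_id"),
                     subset = attr(r, "subset"),
                     chain = attr(r, "chain"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Reshape a feature matrix for PCA
#'
#' One row per (donor, subset) sample. With `layout = "concatenate"`
#' (default) and both chains present, TRA and TRB features are laid out
#' side by side with `TRA_`/`TRB_` prefixes (56 columns); with
#' `layout = "per_chain"`, rows are (donor, subset, chain) with the 28
#' plain columns.
#'
#' @param fm output of [feature_matrix()]
#' @param layout `"concatenate"` or `"per_chain"`
#' @return data.frame of samples x numeric parameters, with metadata
#'   columns first
#' @export
pca_input <- function(fm, layout = c("concatenate", "per_chain")) {
  layout <- match.arg(layout)
  chains <- sort(unique(fm$chain))
  if (layout == "per_chain" || length(chains) == 1L) {
    meta <- fm[, c("donor_id", "subset", "chain"), drop = FALSE]
    return(cbind(meta, fm[, FEATURE_NAMES, drop = FALSE]))
  }
  wide <- NULL
  for (ch in chains) {
    sub <- fm[fm$chain == ch, , drop = FALSE]
    val <- sub[, FEATURE_NAMES, drop = FALSE]
    names(val) <- paste(ch, FEATURE_NAMES, sep = "_")
    val <- cbind(sub[, c("donor_id", "subset")], val)
    wide <- if (is.null(wide)) val else
      merge(wide, val, by = c("donor_id", "subset"), sort = TRUE)
  }
  wide
}
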