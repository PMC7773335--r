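SIM_SUBSETS <- c("Tfh", "Th1", "Th1-17", "Th17", "Th22", "Th2a", "Th2", "Treg")

#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the simulator in one validated object. Defaults
#' describe a small but realistic effector/memory cohort: 5 donors, the 8
#' canonical CD4+ subsets, heavy-tailed (log-normal) clone sizes, CDR3
#' lengths between 8 and 20 amino acids peaked near 14-15, Poisson N
#' additions at each junction, and no planted sharing or publicity unless
#' requested.
#'
#' @param n_donors number of donors (default 5)
#' @param subsets character vector of subset labels (default the 8
#'   effector/memory subsets)
#' @param clones_per_subset clonotypes per (donor, subset) repertoire
#' @param chain "TRA" or "TRB"
#' @param clone_size_model list: `type = "lognormal"` with `meanlog`,
#'   `sdlog`, or `type = "powerlaw"` with exponent `alpha` (> 1)
#' @param cdr3_aa_length_model named numeric vector of probabilities over
#'   amino-acid lengths (names = lengths); default a discretized normal
#'   over 8..20 centered at 14.5
#' @param composition_bias named list, subset label -> named numeric of
#'   target mean shifts delta on property scales, applied to the
#'   middle-5 residue sampling weights by exponential tilting
#' @param n_insertion_model named list, subset label -> c(vd, dj) Poisson
#'   means for the V-D and D-J N additions; `.default` supplies the rest
#' @param sharing_matrix square matrix (subset x subset, zero diagonal)
#'   of per-donor probabilities that a clonotype of subset i is
#'   replicated into subset j
#' @param public_fraction probability q that a clonotype's cdr3aa is
#'   drawn from a cohort-shared pool (identical amino-acid sequence
#'   across donors, codons redrawn per donor)
#' @param public_pool_size size of the shared pool per subset; default
#'   scales with demand
#' @param d_undefined_prob fraction of clonotypes without a D-segment
#'   call (markers -1), default 0.05
#' @param seed integer; fully determines the generated cohort
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_donors = 5L,
                             subsets = SIM_SUBSETS,
                             clones_per_subset = 1000L,
                             chain = "TRB",
                             clone_size_model = list(type = "lognormal",
                                                     meanlog = 1, sdlog = 1.2),
                             cdr3_aa_length_model = NULL,
                             composition_bias = list(),
                             n_insertion_model = list(.default = c(vd = 3, dj = 3)),
                             sharing_matrix = NULL,
                             public_fraction = 0,
                             public_pool_size = NULL,
                             d_undefined_prob = 0.05,
                             seed = 1L) {
  if (is.null(cdr3_aa_length_model)) {
    lens <- 8:20
    p <- stats::dnorm(lens, mean = 14.5, sd = 2)
    cdr3_aa_length_model <- setNames(p / sum(p), lens)
  }
  if (is.null(sharing_matrix)) {
    sharing_matrix <- matrix(0, length(subsets), length(subsets),
                             dimnames = list(subsets, subsets))
  }
  cfg <- list(n_donors = as.integer(n_donors), subsets = subsets,
              clones_per_subset = as.integer(clones_per_subset),
              chain = chain, clone_size_model = clone_size_model,
              cdr3_aa_length_model = cdr3_aa_length_model,
              composition_bias = composition_bias,
              n_insertion_model = n_insertion_model,
              sharing_matrix = sharing_matrix,
              public_fraction = public_fraction,
              public_pool_size = public_pool_size,
              d_undefined_prob = d_undefined_prob,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_donors >= 1L, length(cfg$subsets) >= 1L,
            cfg$clones_per_subset >= 1L)
  sm <- cfg$sharing_matrix
  if (!is.matrix(sm) || nrow(sm) != length(cfg$subsets) ||
      ncol(sm) != length(cfg$subsets))
    stop("sharing_matrix must be a square subset x subset matrix")
  if (any(sm < 0 | sm > 1)) stop("sharing probabilities must lie in [0, 1]")
  if (any(diag(sm) != 0)) stop("sharing_matrix diagonal must be zero")
  if (cfg$public_fraction < 0 || cfg$public_fraction > 1)
    stop("public_fraction must lie in [0, 1]")
  if (abs(sum(cfg$cdr3_aa_length_model) - 1) > 1e-8)
    stop("cdr3_aa_length_model probabilities must sum to 1")
  bad <- setdiff(names(cfg$composition_bias), cfg$subsets)
  if (length(bad)) stop("composition_bias for unknown subset(s): ",
                        paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Solve exponential-tilting weights for a target mean shift
#'
#' Given scale values `s(aa)` and base sampling weights `w(aa)`, finds
#' `beta` such that residues drawn with probability proportional to
#' `w(aa) * exp(beta * s(aa))` have mean scale value equal to the base
#' mean plus `delta`. Monotone in `beta`, solved with [stats::uniroot()].
#'
#' @param scale_values named numeric over the 20 amino acids
#' @param delta target shift of the mean
#' @param base_weights base weights (default uniform)
#' @return list: `weights` (normalized), `beta`, `target_mean`
#' @export
tilt_weights <- function(scale_values, delta, base_weights = NULL) {
  s <- as.numeric(scale_values)
  w0 <- if (is.null(base_weights)) rep(1 / length(s), length(s))
        else base_weights / sum(base_weights)
  base_mean <- sum(w0 * s)
  target <- base_mean + delta
  if (target <= min(s) || target >= max(s))
    stop(sprintf("target mean %.4g is outside the achievable range (%.4g, %.4g)",
                 target, min(s), max(s)))
  f <- function(beta) {
    w <- w0 * exp(beta * (s - mean(s)))  # centering for numerical stability
    sum(w * s) / sum(w) - target
  }
  beta <- stats::uniroot(f, lower = -200, upper = 200, tol = 1e-12)$root
  w <- w0 * exp(beta * (s - mean(s)))
  list(weights = setNames(w / sum(w), names(scale_values)), beta = beta,
       target_mean = target)
}

sample_clone_sizes <- function(n, model) {
  switch(model$type,
         lognormal = pmax(1, round(stats::rlnorm(n, model$meanlog, model$sdlog))),
         powerlaw = pmax(1, floor(stats::runif(n)^(-1 / (model$alpha - 1)))),
         stop("unknown clone_size_model type: ", model$type))
}

# vectorized random codon choice for a vector of single aa characters
reverse_translate <- function(aa_seqs) {
  gc_tab <- Biostrings::GENETIC_CODE
  cod_by_aa <- split(names(gc_tab), gc_tab)
  aas <- names(cod_by_aa)
  cod_mat <- matrix("", length(aas), max(lengths(cod_by_aa)),
                    dimnames = list(aas, NULL))
  for (a in aas) cod_mat[a, seq_along(cod_by_aa[[a]])] <- cod_by_aa[[a]]
  ncod <- lengths(cod_by_aa)[aas]

  lens <- nchar(aa_seqs)
  id <- rep.int(seq_along(aa_seqs), lens)
  ch <- unlist(strsplit(aa_seqs, "", fixed = TRUE), use.names = FALSE)
  ai <- match(ch, aas)
  pick <- floor(stats::runif(length(ch)) * ncod[ai]) + 1L
  codons <- cod_mat[cbind(ai, pick)]
  vapply(split(codons, id), paste, character(1), collapse = "")
}

sample_middle5 <- function(n, weights) {
  m <- matrix(sample(AA20, n * 5L, replace = TRUE, prob = weights),
              nrow = n)
  do.call(paste0, as.data.frame(m))
}

draw_cdr3aa <- function(n, len_model, mid_weights) {
  lens <- as.integer(sample(names(len_model), n, replace = TRUE,
                            prob = len_model))
  inner <- vapply(lens - 2L, function(L)
    paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  aa <- paste0("C", inner, "F")  # canonical CDR3 anchors
  # overwrite the middle-5 window (the scored region) with tilted draws
  mid <- sample_middle5(n, mid_weights)
  start <- (lens - 5L) %/% 2L + 1L
  substr(aa, start, start + 4L) <- mid
  aa
}

draw_junctions <- function(nt_len, lambda_vd, lambda_dj, d_undefined_prob) {
  n <- length(nt_len)
  vdins <- stats::rpois(n, lambda_vd)
  djins <- stats::rpois(n, lambda_dj)
  d_len <- sample(4:10, n, replace = TRUE)
  # shrink insertions, then D, until V and J keep >= 3 nt each
  room <- nt_len - 6L
  over <- pmax(0L, vdins + djins + d_len - room)
  take_vd <- pmin(vdins, ceiling(over / 2))
  take_dj <- pmin(djins, over - take_vd)
  vdins <- vdins - take_vd; djins <- djins - take_dj
  over <- pmax(0L, vdins + djins + d_len - room)
  d_len <- pmax(1L, d_len - over)
  rest <- nt_len - vdins - djins - d_len
  v_len <- pmax(3L, floor(rest / 2))
  j_len <- rest - v_len
  v_end <- v_len - 1L
  d_start <- v_len + vdins
  d_end <- d_start + d_len - 1L
  j_start <- d_end + djins + 1L
  und <- stats::runif(n) < d_undefined_prob
  d_start[und] <- d_end[und] <- -1L
  data.frame(v_end = v_end, d_start = d_start, d_end = d_end,
             j_start = j_start, vdins_true = vdins, djins_true = djins,
             d_undefined = und)
}

#' Generate a synthetic multi-donor, multi-subset cohort
#'
#' Emits one repertoire per (donor, subset) with known, controllable
#' structure: heavy-tailed clone sizes; CDR3 amino-acid sequences whose
#' middle-5 residues can carry a per-subset physicochemical bias
#' (exponential tilting, see [tilt_weights()]); nucleotide sequences
#' back-generated by random codon choice with junction markers consistent
#' with the drawn V-D/D-J insertion counts; clonotypes replicated between
#' subsets within a donor according to `sharing_matrix` (identical
#' v_gene + cdr3nt); and clonotypes whose cdr3aa comes from a
#' cohort-shared public pool (identical amino-acid sequence across
#' donors, codons independent, so nucleotide overlap and amino-acid
#' publicity stay decoupled). V/D/J names come from a fictional catalog
#' (`TRBV-sim-01`..). The output is fully determined by `cfg$seed`.
#'
#' @param cfg a [generator_config()]
#' @return list with `repertoires` (list named donor|subset) and
#'   `ledger`: ground truth with `shared` (planted inter-subset copies),
#'   `public` (pool draws), and `property_targets` (per-subset expected
#'   middle-5 means for every biased scale)
#' @export
generate_cohort <- function(cfg) {
  validate_generator_config(cfg)
  tab <- aa_property_table()
  with_seed(cfg$seed, {
    donors <- sprintf("D%d", seq_len(cfg$n_donors))
    vcat <- sprintf("%sV-sim-%02d", substr(cfg$chain, 1, 3), 1:30)
    dcat <- sprintf("%sD-sim-%02d", substr(cfg$chain, 1, 3), 1:3)
    jcat <- sprintf("%sJ-sim-%02d", substr(cfg$chain, 1, 3), 1:12)

    # per-subset middle-5 sampling weights and expected means
    mid_weights <- list(); targets <- list()
    for (ss in cfg$subsets) {
      bias <- cfg$composition_bias[[ss]]
      w <- rep(1 / 20, 20)
      if (!is.null(bias)) {
        if (length(bias) != 1L)
          stop("one biased scale per subset is supported (subset ", ss, ")")
        sc <- names(bias)
        tw <- tilt_weights(setNames(tab[[sc]], rownames(tab)), bias[[1L]])
        w <- tw$weights
        targets[[ss]] <- data.frame(subset = ss, scale = sc,
                                    expected_mean = tw$target_mean,
                                    beta = tw$beta)
      }
      mid_weights[[ss]] <- w
    }
    base_means <- vapply(colnames(tab), function(sc) mean(tab[[sc]]),
                         numeric(1))

    # public pools: one per subset, shared across donors
    pools <- list()
    if (cfg$public_fraction > 0) {
      demand <- cfg$clones_per_subset * cfg$public_fraction
      pool_n <- cfg$public_pool_size
      if (is.null(pool_n)) pool_n <- max(20L, ceiling(3 * demand))
      if (pool_n < demand)
        stop("public pool smaller than expected demand: infeasible configuration")
      for (ss in cfg$subsets)
        pools[[ss]] <- draw_cdr3aa(pool_n, cfg$cdr3_aa_length_model,
                                   mid_weights[[ss]])
    }

    ins_model <- function(ss) {
      m <- cfg$n_insertion_model[[ss]]
      if (is.null(m)) m <- cfg$n_insertion_model[[".default"]]
      if (is.null(m)) m <- c(vd = 3, dj = 3)
      m
    }

    reps <- list(); shared_led <- list(); public_led <- list()
    for (d in donors) {
      base <- list()
      for (ss in cfg$subsets) {
        n <- cfg$clones_per_subset
        aa <- draw_cdr3aa(n, cfg$cdr3_aa_length_model, mid_weights[[ss]])
        if (cfg$public_fraction > 0) {
          is_pub <- stats::runif(n) < cfg$public_fraction
          if (any(is_pub)) {
            aa[is_pub] <- sample(pools[[ss]], sum(is_pub), replace = TRUE)
            public_led[[length(public_led) + 1L]] <-
              data.frame(donor_id = d, subset = ss, cdr3aa = aa[is_pub],
                         stringsAsFactors = FALSE)
          }
        }
        nt <- reverse_translate(aa)
        lam <- ins_model(ss)
        jm <- draw_junctions(nchar(nt), lam[["vd"]], lam[["dj"]],
                             cfg$d_undefined_prob)
        df <- data.frame(
          count = sample_clone_sizes(n, cfg$clone_size_model),
          cdr3nt = nt, cdr3aa = aa,
          v_gene = sample(vcat, n, replace = TRUE),
          d_gene = ifelse(jm$d_undefined, "",
                          sample(dcat, n, replace = TRUE)),
          j_gene = sample(jcat, n, replace = TRUE),
          v_end = jm$v_end, d_start = jm$d_start, d_end = jm$d_end,
          j_start = jm$j_start, stringsAsFactors = FALSE)
        base[[ss]] <- df
      }
      # planted inter-subset sharing (identical v_gene + cdr3nt)
      extra <- lapply(cfg$subsets, function(x) NULL)
      names(extra) <- cfg$subsets
      for (i in cfg$subsets) for (j in cfg$subsets) {
        sij <- cfg$sharing_matrix[i, j]
        if (i == j || sij <= 0) next
        pick <- which(stats::runif(nrow(base[[i]])) < sij)
        if (!length(pick)) next
        cp <- base[[i]][pick, , drop = FALSE]
        cp$count <- sample_clone_sizes(nrow(cp), cfg$clone_size_model)
        extra[[j]] <- rbind(extra[[j]], cp)
        shared_led[[length(shared_led) + 1L]] <-
          data.frame(donor_id = d, subset_from = i, subset_to = j,
                     v_gene = cp$v_gene, cdr3nt = cp$cdr3nt,
                     stringsAsFactors = FALSE)
      }
      for (ss in cfg$subsets) {
        df <- rbind(base[[ss]], extra[[ss]])
        reps[[paste(d, ss, sep = "|")]] <-
          suppressMessages(repertoire(df, donor_id = d, subset = ss,
                                      chain = cfg$chain)) |>
          recompute_frequencies()
      }
    }

    ledger <- list(
      shared = if (length(shared_led)) do.call(rbind, shared_led)
               else data.frame(donor_id = character(), subset_from = character(),
                               subset_to = character(), v_gene = character(),
                               cdr3nt = character(), stringsAsFactors = FALSE),
      public = if (length(public_led)) do.call(rbind, public_led)
               else data.frame(donor_id = character(), subset = character(),
                               cdr3aa = character(), stringsAsFactors = FALSE),
      property_targets = if (length(targets)) do.call(rbind, targets)
                         else data.frame(subset = character(), scale = character(),
                                         expected_mean = numeric(), beta = numeric()),
      base_property_means = base_means)
    list(repertoires = reps, ledger = ledger)
  })
}

#' Plant a clonal expansion
#'
#' Moves an extra fraction `mass` of the total frequency onto the current
#' top-k clonotypes: the whole distribution is scaled by `1 - mass` and
#' the freed mass is returned to the top-k block in proportion to its
#' existing frequencies. The result majorizes the input, so the
#' normalized Shannon-Wiener index strictly decreases for every
#' `mass > 0`, and the operation is continuous at `mass -> 0`. Counts are
#' re-materialized on a 10^9-molecule grid so they stay whole numbers
#' while tracking the target frequencies to ~5e-10.
#'
#' @param rep a [repertoire()] with > k clonotypes
#' @param k number of clonotypes to expand
#' @param mass extra total frequency planted on them, in (0, 1)
#' @return repertoire with planted expansion
#' @export
plant_expansion <- function(rep, k = 1L, mass = 0.5) {
  if (mass <= 0 || mass >= 1) stop("mass must lie strictly in (0, 1)")
  if (k < 1L || k >= nrow(rep)) stop("k must lie in [1, n_clonotypes)")
  rep <- recompute_frequencies(rep)
  o <- order(-rep$count, rep$v_gene, rep$cdr3nt, method = "radix")
  top <- o[seq_len(k)]
  f <- rep$freq
  in_mass <- sum(f[top])
  f <- f * (1 - mass)
  f[top] <- f[top] + mass * rep$freq[top] / in_mass
  grid <- 1e9
  rep$count <- pmax(1, round(f * grid))
  recompute_frequencies(rep)
}
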