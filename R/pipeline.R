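#' Pipeline configuration
#'
#' Defaults mirror the standard published protocol: 16,000-molecule
#' downsampling for diversity, top-20,000 truncation for overlap and
#' publicity, top-2,000 for sharing networks, middle-5 CDR3 scoring,
#' frequency weighting.
#'
#' @param n_molecules diversity sampling depth (default 16000)
#' @param top_n_overlap truncation for overlap/publicity (default 20000)
#' @param top_n_network truncation for sharing networks (default 2000)
#' @param middle_k CDR3 middle-region length (default 5)
#' @param weighted frequency weighting for feature averages
#' @param pca_layout `"concatenate"` or `"per_chain"`, see [pca_input()]
#' @param seed RNG seed used for downsampling
#' @return named list of class `pipeline_config`
#' @export
pipeline_config <- function(n_molecules = 16000L, top_n_overlap = 20000L,
                            top_n_network = 2000L, middle_k = 5L,
                            weighted = TRUE,
                            pca_layout = "concatenate", seed = 1L) {
  structure(list(n_molecules = as.integer(n_molecules),
                 top_n_overlap = as.integer(top_n_overlap),
                 top_n_network = as.integer(top_n_network),
                 middle_k = as.integer(middle_k), weighted = weighted,
                 pca_layout = pca_layout, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a sample sheet of clonotype tables
#'
#' The sheet is a TSV with columns `donor_id`, `subset`, `chain`, `path`
#' (paths relative to the sheet's directory or absolute) and optional
#' `dialect` (default "vdjtools").
#'
#' @param sheet_path path to the sample sheet
#' @return list of repertoires named `donor|subset|chain`
#' @export
read_sample_sheet <- function(sheet_path) {
  sheet <- utils::read.table(sheet_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("donor_id", "subset", "chain", "path")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(sheet$dialect)) sheet$dialect <- "vdjtools"
  base <- dirname(normalizePath(sheet_path))
  reps <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_clonotype_table(p, sheet$dialect[i], donor_id = sheet$donor_id[i],
                         subset = sheet$subset[i], chain = sheet$chain[i])
  })
  names(reps) <- paste(sheet$donor_id, sheet$subset, sheet$chain, sep = "|")
  reps
}

write_report <- function(df, path, cfg, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# stage: %s", stage),
               sprintf("# generated: tcrsubsets %s",
                       as.character(utils::packageVersion("tcrsubsets"))),
               sprintf("# params: n_molecules=%d top_n_overlap=%d top_n_network=%d middle_k=%d weighted=%s seed=%d",
                       cfg$n_molecules, cfg$top_n_overlap, cfg$top_n_network,
                       cfg$middle_k, cfg$weighted, cfg$seed)), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

rep_meta <- function(r)
  c(donor = attr(r, "donor_id"), subset = attr(r, "subset"),
    chain = attr(r, "chain"))

#' Run the full repertoire-comparison pipeline
#'
#' Orchestrates the paper-shaped analysis over a set of repertoires:
#' feature vectors (with group-versus-mean statistics per feature),
#' diversity at fixed depth, pairwise within-donor overlap, cross-donor
#' publicity per subset, per-donor sharing networks, and PCA over the
#' feature matrix. Writes seven TSV reports (`features.tsv`,
#' `stats.tsv`, `diversity.tsv`, `overlap.tsv`, `publicity.tsv`,
#' `network_nodes.tsv`/`network_edges.tsv`, `pca_scores.tsv` +
#' `pca_loadings.tsv`), each with a commented parameter header. Stages
#' whose preconditions fail (a single subset, too few donors, shallow
#' repertoires) are skipped with a logged reason rather than failing the
#' run.
#'
#' @param reps list of repertoires (e.g. from [read_sample_sheet()] or
#'   [generate_cohort()])
#' @param out_dir output directory, created if missing
#' @param cfg a [pipeline_config()]
#' @return invisibly, a list of the report data.frames and a character
#'   vector `log`
#' @export
run_pipeline <- function(reps, out_dir, cfg = pipeline_config()) {
  stopifnot(length(reps) >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logline <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    logline <<- c(logline, msg)
  }
  meta <- as.data.frame(do.call(rbind, lapply(reps, rep_meta)),
                        stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  out <- list()
  t0 <- proc.time()[["elapsed"]]

  # features + per-feature statistics
  fm <- feature_matrix(reps, weighted = cfg$weighted, k = cfg$middle_k)
  out$features <- fm
  write_report(fm, file.path(out_dir, "features.tsv"), cfg, "features")
  say("features: %d repertoires x %d parameters", nrow(fm),
      length(FEATURE_NAMES))

  stats_rows <- list()
  if (length(unique(fm$subset)) >= 2L) {
    for (ch in unique(fm$chain)) {
      sub <- fm[fm$chain == ch, , drop = FALSE]
      counts <- table(sub$subset)
      if (sum(counts >= 2L) < 2L) next
      for (feat in FEATURE_NAMES) {
        if (anyNA(sub[[feat]])) next
        byg <- split(sub[[feat]], sub$subset)
        res <- tryCatch(
          suppressWarnings(group_vs_mean_tests(byg)),
          error = function(e) NULL)
        if (is.null(res)) next
        pg <- res$per_group
        pg$chain <- ch; pg$feature <- feat
        pg$omnibus_method <- res$omnibus$method
        pg$omnibus_p <- res$omnibus$p
        stats_rows[[length(stats_rows) + 1L]] <- pg
      }
    }
  }
  if (length(stats_rows)) {
    st <- do.call(rbind, stats_rows)
    st <- st[, c("chain", "feature", "omnibus_method", "omnibus_p",
                 "group", "n", "statistic", "p", "p_adj", "tier")]
    out$stats <- st
    write_report(st, file.path(out_dir, "stats.tsv"), cfg, "stats")
    say("stats: %d group tests", nrow(st))
  } else say("stats: skipped (need >= 2 subsets with >= 2 donors)")

  # diversity at fixed depth; shallow samples excluded, not upsampled
  div_rows <- list()
  for (i in seq_along(reps)) {
    r <- reps[[i]]
    if (total_count(r) < cfg$n_molecules) {
      say("diversity: %s excluded (%d < %d molecules)", names(reps)[i],
          total_count(r), cfg$n_molecules)
      next
    }
    d <- diversity_stats(r, cfg$n_molecules, seed = cfg$seed + i)
    m1 <- meta[i, , drop = FALSE]
    rownames(m1) <- NULL
    div_rows[[length(div_rows) + 1L]] <- cbind(m1, d)
  }
  if (length(div_rows)) {
    dv <- do.call(rbind, div_rows)
    out$diversity <- dv
    write_report(dv, file.path(out_dir, "diversity.tsv"), cfg, "diversity")
    say("diversity: %d samples at %d molecules", nrow(dv), cfg$n_molecules)
  } else say("diversity: skipped (no sample reaches n_molecules)")

  # within-donor pairwise overlap + sharing networks
  ov_rows <- list(); node_rows <- list(); edge_rows <- list()
  for (d in unique(meta$donor)) for (ch in unique(meta$chain)) {
    ix <- which(meta$donor == d & meta$chain == ch)
    if (length(ix) < 2L) next
    rr <- reps[ix]
    names(rr) <- meta$subset[ix]
    ov <- repertoire_overlap(rr, top_n = cfg$top_n_overlap)
    ov <- cbind(donor = d, chain = ch, ov)
    ov_rows[[length(ov_rows) + 1L]] <- ov
    net <- build_sharing_network(rr, top_n = cfg$top_n_network)
    node_rows[[length(node_rows) + 1L]] <- cbind(donor = d, net$nodes)
    if (nrow(net$edges))
      edge_rows[[length(edge_rows) + 1L]] <- cbind(donor = d, net$edges)
  }
  if (length(ov_rows)) {
    ov <- do.call(rbind, ov_rows)
    out$overlap <- ov
    write_report(ov, file.path(out_dir, "overlap.tsv"), cfg, "overlap")
    nodes <- do.call(rbind, node_rows)
    edges <- if (length(edge_rows)) do.call(rbind, edge_rows)
             else data.frame(donor = character(), source = character(),
                             target = character(), v_gene = character(),
                             cdr3nt = character())
    out$network_nodes <- nodes; out$network_edges <- edges
    write_report(nodes, file.path(out_dir, "network_nodes.tsv"), cfg, "network")
    write_report(edges, file.path(out_dir, "network_edges.tsv"), cfg, "network")
    say("overlap: %d pairs; network: %d nodes, %d edges", nrow(ov),
        nrow(nodes), nrow(edges))
  } else say("overlap/network: skipped (need >= 2 subsets per donor)")

  # cross-donor publicity per subset
  pub_rows <- list()
  for (ss in unique(meta$subset)) for (ch in unique(meta$chain)) {
    ix <- which(meta$subset == ss & meta$chain == ch)
    if (length(ix) < 2L) next
    rr <- reps[ix]
    names(rr) <- meta$donor[ix]
    pub <- publicity_matrix(rr, top_n = cfg$top_n_overlap)
    pub_rows[[length(pub_rows) + 1L]] <- cbind(chain = ch, pub)
  }
  if (length(pub_rows)) {
    pub <- do.call(rbind, pub_rows)
    out$publicity <- pub
    write_report(pub, file.path(out_dir, "publicity.tsv"), cfg, "publicity")
    say("publicity: %d donor pairs", nrow(pub))
  } else say("publicity: skipped (need >= 2 donors per subset)")

  # PCA over the feature matrix
  pin <- pca_input(fm, cfg$pca_layout)
  num <- pin[, !(names(pin) %in% c("donor_id", "subset", "chain")),
             drop = FALSE]
  if (nrow(pin) >= 3L && !anyNA(num)) {
    pca <- suppressWarnings(pca_features(num))
    sco <- cbind(pin[, intersect(c("donor_id", "subset", "chain"),
                                 names(pin)), drop = FALSE],
                 as.data.frame(pca$scores))
    load <- data.frame(parameter = rownames(pca$loadings),
                       as.data.frame(pca$loadings))
    evr <- data.frame(component = colnames(pca$scores),
                      explained_variance_ratio = pca$explained_variance_ratio)
    out$pca_scores <- sco; out$pca_loadings <- load; out$pca_variance <- evr
    write_report(sco, file.path(out_dir, "pca_scores.tsv"), cfg, "pca")
    write_report(load, file.path(out_dir, "pca_loadings.tsv"), cfg, "pca")
    write_report(evr, file.path(out_dir, "pca_variance.tsv"), cfg, "pca")
    say("pca: %d samples, PC1 %.1f%%", nrow(sco),
        100 * pca$explained_variance_ratio[1L])
  } else say("pca: skipped (need >= 3 complete samples)")

  say("pipeline done in %.1f s", proc.time()[["elapsed"]] - t0)
  writeLines(logline, file.path(out_dir, "pipeline.log"))
  out$log <- logline
  invisible(out)
}
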