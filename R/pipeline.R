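#' Run the full LDS pipeline
#'
#' Edge list in, ranking and evaluation out: LFFD for every node, Bayes
#' compartment scores trained on the supplied reference sets, per-protein
#' SCS over the network's nodes, the LDS fusion at `alpha`, and (when
#' essentials are given) a full evaluation. Inputs may be in-memory tibbles/
#' vectors or file paths (edge list TSV, annotation TSV, one-ID-per-line
#' lists).
#'
#' @param edges Edge tibble or path to an edge-list TSV.
#' @param annotations Annotation tibble or path (see [read_annotations()]).
#' @param essentials,nonessentials Character vectors or paths to
#'   one-ID-per-line files. Used both to train the compartment scores and
#'   (essentials) as evaluation labels.
#' @param alpha Topology weight in `[0, 1]`.
#' @param cutoff Classification cutoff for metrics.
#' @param top_k Top-k grid for enrichment counts.
#' @param out_dir If non-NULL, writes `ranking.tsv`,
#'   `compartment_scores.tsv`, and `evaluation.tsv` there.
#' @return (Invisibly) list with `ranking` (an `lds_ranking`),
#'   `compartment_scores`, `scs`, `evaluation`.
#' @export
run_lds <- function(edges, annotations, essentials, nonessentials,
                    alpha = 0.5, cutoff = 1500,
                    top_k = seq(1000, 1500, 100), out_dir = NULL) {
  edges <- if (is.character(edges)) read_edge_list(edges) else edges
  annotations <- if (is.character(annotations) && length(annotations) == 1L) {
    read_annotations(annotations)
  } else annotations
  essentials <- read_id_list(essentials)
  nonessentials <- read_id_list(nonessentials)
  nodes <- network_nodes(edges)

  fractal <- fractal_dimensions(edges)
  ctable <- compartment_scores(annotations, essentials, nonessentials)
  scs <- protein_scs(annotations, ctable, proteins = nodes)
  ranking <- lds_scores(fractal, scs, alpha = alpha, edges = edges)
  evaluation <- evaluate_ranking(ranking, essentials, ks = top_k,
                                 cutoff = min(cutoff, length(nodes)))
  inform(sprintf("ranked %d proteins (alpha = %g); %d unannotated (SCS = 0)",
                 nrow(ranking), alpha, sum(scs$scs == 0)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tidy(ranking), file.path(out_dir, "ranking.tsv"))
    readr::write_tsv(as_tibble(ctable), file.path(out_dir, "compartment_scores.tsv"))
    readr::write_tsv(dplyr::bind_cols(
      tidyr::pivot_wider(evaluation$topk, names_from = "k",
                         values_from = "essential_count",
                         names_prefix = "top"),
      evaluation$metrics), file.path(out_dir, "evaluation.tsv"))
  }
  invisible(list(ranking = ranking, compartment_scores = ctable, scs = scs,
                 evaluation = evaluation))
}

#' Compare LDS against baseline centralities
#'
#' Ranks the network with each requested method (the seven baselines plus
#' `"LDS"`), evaluates each ranking against the essential labels, and
#' returns per-method rankings with a combined metrics table.
#'
#' @inheritParams run_lds
#' @param methods Method names: any of `names(baseline_methods)` plus
#'   `"LDS"`.
#' @return (Invisibly) list with `rankings` (named list of ordered ID
#'   vectors) and `evaluation` (tibble, one row per method). With `out_dir`,
#'   writes `ranking_<method>.tsv` per method and `comparison.tsv`.
#' @export
run_compare <- function(edges, annotations = NULL, essentials,
                        nonessentials = NULL,
                        methods = c("DC", "LDS"), alpha = 0.5, cutoff = 1500,
                        top_k = seq(1000, 1500, 100), out_dir = NULL) {
  if (length(methods) == 0) abort("no methods requested")
  known <- c(names(baseline_methods), "LDS")
  unknown <- setdiff(methods, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown method %s; available: %s", shQuote(unknown[1]),
                  paste(known, collapse = ", ")))
  }
  if ("LDS" %in% methods && (is.null(annotations) || is.null(nonessentials))) {
    abort("method LDS needs annotations and a non-essential reference set")
  }
  edges <- if (is.character(edges)) read_edge_list(edges) else edges
  essentials <- read_id_list(essentials)
  deg <- degree_centrality(edges)

  rankings <- lapply(setNames(methods, methods), function(mname) {
    if (mname == "LDS") {
      run_lds(edges, annotations, essentials, nonessentials, alpha = alpha,
              cutoff = cutoff, top_k = top_k)$ranking$protein
    } else {
      sc <- baseline_methods[[mname]](edges)
      sc$degree <- deg$score[match(sc$protein, deg$protein)]
      rank_proteins(sc)
    }
  })
  evaluation <- purrr::map(methods, function(mname) {
    ev <- evaluate_ranking(rankings[[mname]], essentials, ks = top_k,
                           cutoff = min(cutoff, length(rankings[[mname]])))
    dplyr::bind_cols(tibble(method = mname), ev$metrics)
  }) |> bind_rows()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mname in methods) {
      readr::write_tsv(tibble(rank = seq_along(rankings[[mname]]),
                              protein = rankings[[mname]]),
                       file.path(out_dir, paste0("ranking_", mname, ".tsv")))
    }
    readr::write_tsv(evaluation, file.path(out_dir, "comparison.tsv"))
  }
  invisible(list(rankings = rankings, evaluation = evaluation))
}

#' Write a simulated dataset to a directory
#'
#' Plain-TSV serialization of [simulate_ppi_dataset()]: `edges.tsv`,
#' `essentials.txt`, `nonessentials.txt`, `annotations.tsv`.
#'
#' @param dataset Result of [simulate_ppi_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ppi_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(dataset$edges, file.path(dir, "edges.tsv"))
  writeLines(dataset$essentials, file.path(dir, "essentials.txt"))
  writeLines(dataset$nonessentials, file.path(dir, "nonessentials.txt"))
  ann <- dataset$annotations
  ann$compartment[is.na(ann$compartment)] <- ""
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"), col_names = FALSE)
  invisible(dir)
}

read_id_list <- function(x) {
  if (length(x) == 1L && is.character(x) && !grepl("[\t\n]", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  x <- trimws(as.character(x))
  unique(x[nzchar(x)])
}
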