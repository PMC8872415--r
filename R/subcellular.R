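#' The default subcellular compartment vocabulary
#'
#' The 11 yeast compartments the COMPARTMENTS database groups localization
#' evidence into. Annotation tables are validated against this vocabulary by
#' default; supply your own vector to work with a different one.
#'
#' @format Character vector of 11 compartment names.
#' @export
yeast_compartments <- c(
  "Cytoskeleton", "Cytosol", "Endoplasmic Reticulum", "Endosome",
  "Extracellular space", "Golgi apparatus", "Mitochondrion", "Nucleus",
  "Peroxisome", "Plasma membrane", "Vacuole"
)

#' Read a protein-to-compartment annotation table
#'
#' TSV lines: a protein identifier, then one compartment name per additional
#' field; semicolon-joined names within a field are also accepted. A line
#' with only an identifier marks the protein as annotated with no
#' compartment. Repeated lines for a protein are merged by union.
#'
#' @param file Path or character vector of lines.
#' @param compartments Allowed compartment names; anything else is rejected
#'   with its line number.
#' @return A tibble with columns `protein`, `compartment` (one row per
#'   protein-compartment pair; `NA` compartment for unannotated proteins).
#' @export
read_annotations <- function(file, compartments = yeast_compartments) {
  lines <- if (length(file) == 1L && !grepl("[\t\n]", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    as.character(file)
  }
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  rows <- purrr::map2(lines, lineno, function(line, ln) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    protein <- fields[1]
    comps <- unlist(strsplit(fields[-1], ";", fixed = TRUE))
    comps <- trimws(comps[nzchar(trimws(comps))])
    bad <- setdiff(comps, compartments)
    if (length(bad) > 0) {
      abort(sprintf("line %d: unknown compartment %s for protein %s",
                    ln, shQuote(bad[1]), shQuote(protein)))
    }
    if (length(comps) == 0) tibble(protein = protein, compartment = NA_character_)
    else tibble(protein = protein, compartment = comps)
  })
  ann <- bind_rows(rows)
  if (nrow(ann) == 0L) {
    return(tibble(protein = character(), compartment = character()))
  }
  # union across duplicate lines; a protein with any real compartment loses its NA marker
  ann <- distinct(ann)
  annotated <- unique(ann$protein[!is.na(ann$compartment)])
  ann |>
    filter(!(is.na(.data$compartment) & .data$protein %in% annotated)) |>
    arrange(.data$protein, .data$compartment)
}

#' Per-compartment essentiality scores by the Bayes formula
#'
#' Given a reference universe of known essential and non-essential proteins
#' and their compartment annotations, estimates for each compartment `C` the
#' posterior probability that a protein found in `C` is essential:
#'
#' \deqn{P(E|C) = \frac{P(E)\,P(C|E)}{P(E)\,P(C|E) + P(NE)\,P(C|NE)}}
#'
#' with `P(C|E)` the fraction of essential proteins annotated to `C` (a
#' multi-compartment protein counts once in each of its compartments), and
#' the prior `P(E)` the essential fraction of the reference universe.
#' Compartments nobody is annotated to have `P(C) = 0`; their score is
#' defined as 0 with a warning.
#'
#' @param annotations Annotation tibble (`protein`, `compartment`), e.g. from
#'   [read_annotations()] or [plant_annotations()].
#' @param essential,nonessential Disjoint, non-empty character vectors of
#'   protein identifiers forming the reference universe. Annotations for
#'   proteins outside the universe are ignored.
#' @param compartments Compartment vocabulary (rows are emitted for every
#'   name, annotated or not).
#' @return A `compartment_score_table`: tibble with one row per compartment
#'   and columns `compartment`, `n_essential`, `n_nonessential`,
#'   `p_c_given_e`, `p_c_given_ne`, `p_c`, `score`; the universe sizes and
#'   priors are attached as attributes and reported by [glance()].
#' @export
compartment_scores <- function(annotations, essential, nonessential,
                               compartments = yeast_compartments) {
  essential <- unique(as.character(essential))
  nonessential <- unique(as.character(nonessential))
  if (length(essential) == 0L || length(nonessential) == 0L) {
    abort("both the essential and non-essential reference sets must be non-empty")
  }
  overlap <- intersect(essential, nonessential)
  if (length(overlap) > 0L) {
    abort(sprintf("essential and non-essential sets overlap (e.g. %s)",
                  shQuote(overlap[1])))
  }
  ann <- annotations |>
    filter(!is.na(.data$compartment)) |>
    distinct(.data$protein, .data$compartment)
  n_e <- length(essential)
  n_ne <- length(nonessential)
  p_e <- n_e / (n_e + n_ne)
  p_ne <- n_ne / (n_e + n_ne)
  tab <- tibble(compartment = compartments) |>
    mutate(
      n_essential = map_int(.data$compartment, function(cc) {
        sum(ann$protein[ann$compartment == cc] %in% essential)
      }),
      n_nonessential = map_int(.data$compartment, function(cc) {
        sum(ann$protein[ann$compartment == cc] %in% nonessential)
      }),
      p_c_given_e = .data$n_essential / n_e,
      p_c_given_ne = .data$n_nonessential / n_ne,
      p_c = p_e * .data$p_c_given_e + p_ne * .data$p_c_given_ne,
      score = ifelse(.data$p_c > 0, p_e * .data$p_c_given_e / .data$p_c, 0)
    )
  n_empty <- sum(tab$p_c == 0)
  if (n_empty > 0) {
    warn(sprintf("%d compartment(s) with no annotated reference protein; score set to 0", n_empty))
  }
  structure(tab, class = c("compartment_score_table", class(tab)),
            n_essential = n_e, n_nonessential = n_ne, p_e = p_e, p_ne = p_ne)
}

#' @rdname compartment_scores
#' @param x A `compartment_score_table`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.compartment_score_table <- function(x, ...) {
  tibble(n_essential = attr(x, "n_essential"),
         n_nonessential = attr(x, "n_nonessential"),
         p_e = attr(x, "p_e"), p_ne = attr(x, "p_ne"),
         n_compartments = nrow(x))
}

#' Subcellular compartment score of each protein
#'
#' SCS(v): the arithmetic mean of the compartment scores `P(E|C)` over the
#' compartments protein `v` is annotated to; 0 for proteins with no
#' compartment (the null-annotation rule) and for proteins absent from the
#' annotation table.
#'
#' @inheritParams compartment_scores
#' @param score_table Result of [compartment_scores()].
#' @param proteins Optional universe to score (e.g. the network's node set);
#'   defaults to the proteins appearing in `annotations`.
#' @return Tibble with columns `protein`, `n_compartments`, `scs`.
#' @export
protein_scs <- function(annotations, score_table, proteins = NULL) {
  ann <- annotations |> filter(!is.na(.data$compartment))
  scored <- ann |>
    left_join(score_table[c("compartment", "score")], by = "compartment") |>
    group_by(.data$protein) |>
    summarise(n_compartments = n(), scs = mean(.data$score))
  if (is.null(proteins)) proteins <- unique(annotations$protein)
  tibble(protein = sort(unique(as.character(proteins)))) |>
    left_join(scored, by = "protein") |>
    mutate(n_compartments = ifelse(is.na(.data$n_compartments), 0L, .data$n_compartments),
           scs = ifelse(is.na(.data$scs), 0, .data$scs))
}
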