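#' Lineage gene death rate
#'
#' The death rate V_D of a lineage is the number of species-specific loss
#' events divided by the time elapsed since the lineage's latest
#' divergence, in events per million years. Display rounds to one
#' decimal (half away from zero); the unrounded value is kept.
#'
#' @param count species-specific event count (non-negative integer).
#' @param divergence_time time since the latest divergence, Myr (> 0).
#' @param species optional species id recorded on the result.
#' @return data.frame with `species`, `count`, `time_myr`, `vd`
#'   (unrounded) and `vd_reported` (1 decimal).
#' @examples
#' computeDeathRate(26, 40)$vd_reported  # 0.7
#' @export
computeDeathRate <- function(count, divergence_time, species = NA_character_) {
  if (count < 0) stop("event count must be non-negative")
  if (divergence_time <= 0) stop("divergence time must be positive")
  vd <- count / divergence_time
  data.frame(species = species, count = count, time_myr = divergence_time,
             vd = vd, vd_reported = roundHalfUp(vd, 1),
             stringsAsFactors = FALSE)
}

#' Mean gene death rate over lineages
#'
#' Arithmetic mean of the unrounded per-lineage rates.
#'
#' @param rates data.frame rbind of [computeDeathRate()] rows.
#' @return list with `mean_vd` (unrounded) and `mean_vd_reported`.
#' @export
meanDeathRate <- function(rates) {
  if (nrow(rates) == 0L) stop("no rates supplied")
  m <- mean(rates$vd)
  list(mean_vd = m, mean_vd_reported = roundHalfUp(m, 1))
}

#' Annotate lost genes with the GO slim terms of their counterparts
#'
#' The lost gene itself has no annotation, so its original function is
#' inferred as the union of the GO slim terms of its orthologous
#' counterparts in the reference annotation species (Arabidopsis in the
#' grass design). Events with no mapped counterpart are flagged
#' unannotated.
#'
#' @param events events data.frame.
#' @param go_map named list gene id -> term ids ([readGoMap()]).
#' @return named list (by `group_id`) of term-id vectors; attribute
#'   `unannotated` lists group ids with no mapped counterpart.
#' @export
annotateLostFunctions <- function(events, go_map) {
  out <- list(); unann <- character(0)
  for (i in seq_len(nrow(events))) {
    cps <- strsplit(events$counterparts[i], ";", fixed = TRUE)[[1]]
    terms <- unique(unlist(go_map[intersect(cps, names(go_map))],
                           use.names = FALSE))
    g <- events$group_id[i]
    if (length(terms)) out[[g]] <- terms else {
      out[[g]] <- character(0); unann <- c(unann, g)
    }
  }
  attr(out, "unannotated") <- unann
  out
}

#' GO slim over-representation among lost genes
#'
#' Per term, a one-sided Fisher's exact test of the 2x2 table contrasting
#' lost genes against the species' background gene set, in-term versus
#' not. Expected lost count is (number of annotated lost genes) x (term
#' fraction in background); the reported ratio is observed/expected
#' rounded half-up to one decimal. Benjamini-Hochberg correction across
#' all tested terms.
#'
#' @param lost_sets list of term-id vectors, one per lost gene (e.g. from
#'   [annotateLostFunctions()]); empty sets are ignored.
#' @param background named list gene id -> term ids for the species.
#' @param term_names optional named vector of term display names.
#' @return data.frame: `term_id`, `term_name`, `observed`, `expected`,
#'   `ratio` (unrounded), `ratio_reported`, `p`, `q`,
#'   `background_missing` (term seen only among lost genes).
#' @export
enrichGoSlim <- function(lost_sets, background, term_names = NULL) {
  if (!length(background)) stop("background must be nonempty")
  lost_sets <- lost_sets[lengths(lost_sets) > 0]
  n_lost <- length(lost_sets)
  N <- length(background)
  bg_terms <- table(unlist(lapply(background, unique), use.names = FALSE))
  family <- names(bg_terms)
  extra <- setdiff(unique(unlist(lost_sets, use.names = FALSE)), family)
  terms <- c(family, extra)
  lost_counts <- table(unlist(lapply(lost_sets, unique), use.names = FALSE))
  rows <- lapply(terms, function(tm) {
    a <- if (tm %in% names(lost_counts)) as.integer(lost_counts[[tm]]) else 0L
    b <- if (tm %in% names(bg_terms)) as.integer(bg_terms[[tm]]) else 0L
    expected <- n_lost * b / N
    p <- stats::fisher.test(matrix(c(a, n_lost - a, b, N - b), nrow = 2,
                                   byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(term_id = tm, observed = a, expected = expected,
               ratio = if (expected > 0) a / expected else NA_real_,
               p = p, background_missing = !(tm %in% family),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- p.adjust(res$p, method = "BH")
  res$ratio_reported <- roundHalfUp(res$ratio, 1)
  res$term_name <- if (!is.null(term_names))
    unname(term_names[res$term_id]) else NA_character_
  res[order(res$q, res$p),
      c("term_id", "term_name", "observed", "expected", "ratio",
        "ratio_reported", "p", "q", "background_missing")]
}
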