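#' Per-interval state distribution
#'
#' For each interval of the timeline, the relative frequency of every state
#' of the dimension's alphabet (frequencies sum to 1 per interval), overall
#' or stratified by cluster. This is the tabular twin of a state distribution
#' plot.
#'
#' @param states state matrix (patients x intervals).
#' @param group optional cluster labels (one per patient).
#' @return data.frame with `interval_index`, `state`, `frequency` (and
#'   `group` when stratified).
#' @export
state_distribution <- function(states, group = NULL) {
  if (is.null(dim(states)) || nrow(states) == 0)
    stop("state_distribution needs a nonempty state matrix", call. = FALSE)
  alphabet <- sort(unique(as.vector(states)))
  one <- function(sub) {
    freq <- vapply(seq_len(ncol(sub)), function(j) {
      tabulate(factor(sub[, j], levels = alphabet), length(alphabet)) / nrow(sub)
    }, numeric(length(alphabet)))
    data.frame(interval_index = rep(seq_len(ncol(sub)), each = length(alphabet)),
               state = rep(alphabet, ncol(sub)),
               frequency = as.vector(freq), stringsAsFactors = FALSE)
  }
  if (is.null(group)) return(one(states))
  group <- as.factor(group)
  out <- lapply(levels(group), function(g) {
    cbind(one(states[group == g, , drop = FALSE]), group = g)
  })
  do.call(rbind, out)
}

#' Stacked-bar state distribution plot
#'
#' @param distribution output of [state_distribution()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_state_distribution <- function(distribution, title = "State distribution") {
  p <- ggplot2::ggplot(distribution,
                       ggplot2::aes(x = .data$interval_index, y = .data$frequency,
                                    fill = .data$state)) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::labs(x = "interval", y = "relative frequency", title = title) +
    ggplot2::theme_minimal()
  if ("group" %in% names(distribution))
    p <- p + ggplot2::facet_wrap(~group)
  p
}

#' Most frequent full sequences
#'
#' Counts distinct whole-trajectory sequences, ordered by descending count
#' (ties broken lexicographically by the sequence string), and reports each
#' sequence's percentage of the cohort and the cumulative percentage of the
#' top rows. Optionally stratified by cluster.
#'
#' @param states state matrix (patients x intervals).
#' @param n number of top sequences to keep (default 10); `Inf` for the full
#'   table.
#' @param group optional cluster labels.
#' @return data.frame with `sequence`, `count`, `percentage`,
#'   `cumulative_percentage` (and `group`).
#' @export
top_sequences <- function(states, n = 10, group = NULL) {
  one <- function(sub) {
    seqs <- apply(sub, 1, paste, collapse = "-")
    tab <- table(seqs)
    ord <- order(-as.integer(tab), names(tab))
    tab <- tab[ord]
    keep <- seq_len(min(n, length(tab)))
    data.frame(sequence = names(tab)[keep],
               count = as.integer(tab)[keep],
               percentage = 100 * as.integer(tab)[keep] / nrow(sub),
               cumulative_percentage = cumsum(100 * as.integer(tab)[keep] / nrow(sub)),
               stringsAsFactors = FALSE)
  }
  if (is.null(group)) return(one(states))
  group <- as.factor(group)
  do.call(rbind, lapply(levels(group), function(g) {
    cbind(one(states[group == g, , drop = FALSE]), group = g)
  }))
}

#' Horizontal bar plot of the most frequent sequences
#'
#' @param freq_table output of [top_sequences()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_top_sequences <- function(freq_table, title = "Most frequent sequences") {
  freq_table$sequence <- factor(freq_table$sequence,
                                levels = rev(unique(freq_table$sequence)))
  p <- ggplot2::ggplot(freq_table,
                       ggplot2::aes(x = .data$percentage, y = .data$sequence)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of patients", y = NULL, title = title) +
    ggplot2::theme_minimal()
  if ("group" %in% names(freq_table))
    p <- p + ggplot2::facet_wrap(~group, scales = "free_y")
  p
}
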