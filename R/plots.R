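# ggplot2 visualisations for observation matrices, clone trees and fits.

#' Plot an observation matrix as a call heatmap
#'
#' @param object A `clone_obs`.
#' @param ... Unused.
#' @return A ggplot: events on x, samples on y, tiles coloured by call.
#' @export
autoplot.clone_obs <- function(object, ...) {
  df <- tidy(object)
  df$call <- factor(df$call, levels = call_levels())
  df$sample_id <- factor(df$sample_id, levels = rev(rownames(object$calls)))
  df$event_id <- factor(df$event_id, levels = colnames(object$calls))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$event_id, y = .data$sample_id,
                                   fill = .data$call)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(ABSENT = "grey92", SUBCLONAL = "#fdb863",
                                          CLONAL = "#b2182b", UNKNOWN = "grey60"),
                               drop = FALSE) +
    ggplot2::labs(x = "CNA event", y = "sample", fill = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.clone_obs
#' @param obs A `clone_obs`.
#' @export
plot_observation_matrix <- function(obs, ...) autoplot(obs, ...)

# simple layered layout: x = depth from root, y = leaf order
.tree_layout <- function(tree) {
  lab <- setNames(tree$nodes$label, tree$nodes$node_id)
  children <- split(tree$edges$child, tree$edges$parent)
  depth <- setNames(integer(nrow(tree$nodes)), tree$nodes$node_id)
  y <- setNames(numeric(nrow(tree$nodes)), tree$nodes$node_id)
  leaf_counter <- 0
  assign_pos <- function(nd, d) {
    depth[[nd]] <<- d
    ch <- children[[nd]]
    ch <- ch[order(lab[ch])]
    if (is.null(ch) || length(ch) == 0) {
      leaf_counter <<- leaf_counter + 1
      y[[nd]] <<- leaf_counter
    } else {
      for (c in ch) assign_pos(c, d + 1)
      y[[nd]] <<- mean(y[ch])
    }
  }
  assign_pos(tree$root, 0)
  tibble(node_id = names(depth), label = unname(lab[names(depth)]),
         x = as.numeric(depth), y = unname(y[names(depth)]))
}

#' Plot a clone tree
#'
#' @param object A `clone_tree`.
#' @param show_events Annotate edges with the events they gain.
#' @param ... Unused.
#' @return A ggplot of the rooted tree, edges labelled with gained events.
#' @export
autoplot.clone_tree <- function(object, show_events = TRUE, ...) {
  lay <- .tree_layout(object)
  seg <- left_join(
    tibble(parent = object$edges$parent, child = object$edges$child,
           events = vapply(object$edges$events, paste, character(1), collapse = "\n")),
    rename(lay, parent = "node_id", x0 = "x", y0 = "y", plab = "label"),
    by = "parent")
  seg <- left_join(seg, rename(lay, child = "node_id", x1 = "x", y1 = "y",
                               clab = "label"), by = "child")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey40") +
    ggplot2::geom_point(data = lay, ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(data = lay, ggplot2::aes(x = .data$x, y = .data$y,
                                                label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "events gained from root", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
  if (show_events && nrow(seg)) {
    p <- p + ggplot2::geom_text(data = seg,
                                ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                                             y = (.data$y0 + .data$y1) / 2,
                                             label = .data$events),
                                size = 2.6, colour = "grey25", vjust = 1.4)
  }
  p
}

#' @rdname autoplot.clone_tree
#' @param tree A `clone_tree`.
#' @export
plot_clone_tree <- function(tree, ...) autoplot(tree, ...)

#' Plot per-resolution minimal clone counts
#'
#' @param object A `clone_fit`.
#' @param ... Unused.
#' @return A ggplot bar chart of minima across resolutions, with the
#'   reported range marked.
#' @export
autoplot.clone_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$feasible, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resolution, y = .data$min_clones)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = c(object$min_clones, object$max_clones),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "resolution", y = "minimal diagnostic clones") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.clone_fit
#' @param fit A `clone_fit`.
#' @export
plot_clone_range <- function(fit, ...) autoplot(fit, ...)
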