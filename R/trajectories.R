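# Linking wave-specific pattern assignments into per-patient trajectories,
# with absorbing Death/Lost states, and the alluvial export.

#' Link wave-specific patterns into trajectories
#'
#' For each consecutive pair of analysed waves, counts patients flowing from
#' every source pattern to every target pattern, or to the absorbing
#' `Death`/`Lost` nodes when the patient left the cohort in the intervening
#' period. Also builds the long-run table linking each patient's first-wave
#' pattern directly to their final-wave pattern (deaths/losses route to the
#' absorbing node of the first such event). Patterns are re-derived per
#' wave; flows are computed on raw labels, never on pattern names.
#'
#' @param cohort an `mm_cohort`.
#' @param fits list of `mm_fit` objects, one per analysed wave, in wave
#'   order (e.g. baseline, +4y, +8y).
#' @return an object of class `mm_traj`: `flows` (wave_from, node_from,
#'   wave_to, node_to, count, share_of_source_pct) for consecutive pairs,
#'   `longrun` (same columns, first wave to last), `nodes` (per-wave node
#'   sizes), `wave_labels`.
#' @export
link_waves <- function(cohort, fits) {
  if (length(fits) < 2L) stop("need at least two waves of fits", call. = FALSE)
  waves <- vapply(fits, function(f) f$wave, integer(1))
  if (is.unsorted(waves, strictly = TRUE)) {
    stop("fits must be in increasing wave order", call. = FALSE)
  }
  labs <- lapply(fits, function(f) {
    stats::setNames(f$labels, f$included_ids)
  })
  # consistency: a labelled patient must be included at that wave
  for (i in seq_along(fits)) {
    st <- wave_status(cohort, waves[i])
    idx <- match(fits[[i]]$included_ids, cohort$patients$patient_id)
    bad <- fits[[i]]$included_ids[st[idx] != "included"]
    if (length(bad) > 0L) {
      stop("patient labelled at wave ", fits[[i]]$wave_label,
           " but dead/lost there: ", paste(utils::head(bad, 5L), collapse = ", "),
           call. = FALSE)
    }
  }

  target_node <- function(ids, from_i, to_i) {
    st <- wave_status(cohort, waves[to_i])[match(ids, cohort$patients$patient_id)]
    out <- character(length(ids))
    out[st == "dead"] <- "Death"
    out[st == "lost"] <- "Lost"
    inc <- st == "included"
    if (any(inc)) {
      l <- labs[[to_i]][ids[inc]]
      if (anyNA(l)) {
        stop("patient included at wave ", fits[[to_i]]$wave_label,
             " but unlabelled: ",
             paste(utils::head(ids[inc][is.na(l)], 5L), collapse = ", "),
             call. = FALSE)
      }
      out[inc] <- paste0("pattern_", l)
    }
    out
  }
  # route to the absorbing node of the first exit event between two waves
  first_exit <- function(ids, from_i, to_i) {
    out <- rep(NA_character_, length(ids))
    for (w in seq.int(from_i + 1L, to_i)) {
      st <- wave_status(cohort, waves[w])[match(ids, cohort$patients$patient_id)]
      hit <- is.na(out) & st != "included"
      out[hit] <- ifelse(st[hit] == "dead", "Death", "Lost")
    }
    out
  }

  tally <- function(from_i, to_i, direct = TRUE) {
    ids <- fits[[from_i]]$included_ids
    src <- paste0("pattern_", labs[[from_i]][ids])
    if (direct) {
      tgt <- target_node(ids, from_i, to_i)
    } else {
      tgt <- first_exit(ids, from_i, to_i)
      st <- wave_status(cohort, waves[to_i])[match(ids, cohort$patients$patient_id)]
      inc <- is.na(tgt)
      tgt[inc] <- paste0("pattern_", labs[[to_i]][ids[inc]])
    }
    tt <- as.data.frame(table(node_from = src, node_to = tgt),
                        stringsAsFactors = FALSE)
    tt <- tt[tt$Freq > 0L, , drop = FALSE]
    src_tot <- tapply(tt$Freq, tt$node_from, sum)
    data.frame(wave_from = fits[[from_i]]$wave_label,
               node_from = tt$node_from,
               wave_to = fits[[to_i]]$wave_label,
               node_to = tt$node_to,
               count = as.integer(tt$Freq),
               share_of_source_pct = pct(tt$Freq, as.numeric(src_tot[tt$node_from])),
               stringsAsFactors = FALSE, row.names = NULL)
  }

  flows <- do.call(rbind, lapply(seq_len(length(fits) - 1L),
                                 function(i) tally(i, i + 1L, direct = TRUE)))
  longrun <- tally(1L, length(fits), direct = FALSE)

  nodes <- do.call(rbind, lapply(seq_along(fits), function(i) {
    if (fits[[i]]$k < 1L) return(NULL)
    sizes <- tabulate(fits[[i]]$labels, fits[[i]]$k)
    data.frame(wave = rep(fits[[i]]$wave_label, fits[[i]]$k),
               node = paste0("pattern_", seq_len(fits[[i]]$k)),
               size = sizes, stringsAsFactors = FALSE)
  }))
  structure(list(flows = flows, longrun = longrun, nodes = nodes,
                 wave_labels = vapply(fits, function(f) f$wave_label, character(1))),
            class = "mm_traj")
}

#' @export
print.mm_traj <- function(x, ...) {
  cat("Multimorbidity trajectories across waves",
      paste(x$wave_labels, collapse = " -> "), "\n")
  print(x$flows, row.names = FALSE)
  invisible(x)
}

#' Share of a trajectory flow
#'
#' Percentage of patients moving between two nodes, denominated either by
#' the source node's outflow ("went to": what fraction of the source moved
#' to the target) or by the target node's inflow ("came from": what
#' fraction of the target originated in the source).
#'
#' @param traj an `mm_traj`, or a flows data frame with columns
#'   `wave_from`, `node_from`, `node_to`, `count`.
#' @param source,target node names (e.g. `"pattern_1"`, `"Death"`).
#' @param direction `"went_to"` (source-denominated, default) or
#'   `"came_from"` (target-denominated).
#' @param wave_from restrict to flows leaving this wave label; required when
#'   the pair occurs in more than one wave pair.
#' @return a percentage.
#' @export
trajectory_shares <- function(traj, source, target,
                              direction = c("went_to", "came_from"),
                              wave_from = NULL) {
  direction <- match.arg(direction)
  flows <- if (inherits(traj, "mm_traj")) traj$flows else traj
  if (!is.null(wave_from)) flows <- flows[flows$wave_from == wave_from, , drop = FALSE]
  if (length(unique(flows$wave_from)) > 1L) {
    stop("flows span several wave pairs; pass wave_from=", call. = FALSE)
  }
  if (!source %in% flows$node_from) stop("unknown source node: ", source, call. = FALSE)
  if (!target %in% c(flows$node_to, flows$node_from)) {
    stop("unknown target node: ", target, call. = FALSE)
  }
  num <- sum(flows$count[flows$node_from == source & flows$node_to == target])
  denom <- switch(direction,
                  went_to = sum(flows$count[flows$node_from == source]),
                  came_from = sum(flows$count[flows$node_to == target]))
  if (denom == 0) stop("zero denominator for ", direction, call. = FALSE)
  100 * num / denom
}

# Internal: verify flow conservation — each non-absorbing node's outflow
# equals its size. Returns the maximum absolute violation (0 when exact).
trajectory_conservation <- function(traj) {
  viol <- 0
  for (wl in unique(traj$flows$wave_from)) {
    fl <- traj$flows[traj$flows$wave_from == wl, , drop = FALSE]
    out <- tapply(fl$count, fl$node_from, sum)
    sz <- traj$nodes[traj$nodes$wave == wl, , drop = FALSE]
    m <- match(names(out), sz$node)
    viol <- max(viol, abs(as.numeric(out) - sz$size[m]))
  }
  viol
}

#' Export alluvial-plot data and figure
#'
#' Writes `flows.csv` (`wave_from, node_from, wave_to, node_to, count`) and
#' optionally renders an alluvial diagram in which box heights and stripe
#' widths are proportional to patient counts. Returns the computed node
#' geometry so proportionality can be verified programmatically.
#'
#' @param traj an `mm_traj`.
#' @param dir output directory (created if absent).
#' @param render render a figure (default `TRUE`).
#' @param format figure format, `"png"` or `"svg"`.
#' @param include_absorbing include the Death/Lost absorbing nodes
#'   (default `TRUE`).
#' @param longrun use the first-to-last-wave table instead of consecutive
#'   flows.
#' @return invisibly, a list with `coords` (node geometry: wave, node, y0,
#'   y1, height), `flows` (as written) and the output `paths`.
#' @export
export_alluvial <- function(traj, dir, render = TRUE,
                            format = c("png", "svg"),
                            include_absorbing = TRUE, longrun = FALSE) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flows <- if (longrun) traj$longrun else traj$flows
  if (!include_absorbing) {
    flows <- flows[!flows$node_to %in% c("Death", "Lost"), , drop = FALSE]
  }
  flows <- flows[, c("wave_from", "node_from", "wave_to", "node_to", "count")]
  csv_path <- file.path(dir, "flows.csv")
  utils::write.csv(flows, csv_path, row.names = FALSE)
  if (nrow(flows) == 0L) {
    return(invisible(list(coords = NULL, flows = flows, paths = csv_path)))
  }

  # node sizes: outflow at the first wave of each pair, inflow elsewhere
  wl <- unique(c(flows$wave_from, flows$wave_to))
  sizes <- list()
  for (w in wl) {
    out <- flows[flows$wave_from == w, , drop = FALSE]
    inn <- flows[flows$wave_to == w, , drop = FALSE]
    s_out <- if (nrow(out) > 0L) tapply(out$count, out$node_from, sum)
    s_in <- if (nrow(inn) > 0L) tapply(inn$count, inn$node_to, sum)
    # non-absorbing nodes are sized by their outflow; inflow-only nodes
    # (absorbing, or the final wave) by their inflow
    s <- s_in[setdiff(names(s_in), names(s_out))]
    s <- c(s_out, s)
    sizes[[w]] <- data.frame(wave = rep(w, length(s)), node = names(s),
                             size = as.numeric(s), stringsAsFactors = FALSE)
  }
  total <- max(vapply(sizes, function(s) sum(s$size), numeric(1)))
  gap <- 0.02 * total
  coords <- do.call(rbind, lapply(sizes, function(s) {
    s <- s[order(s$node %in% c("Death", "Lost"), s$node), , drop = FALSE]
    y1 <- cumsum(s$size + gap) - gap
    y0 <- y1 - s$size
    cbind(s, y0 = y0, y1 = y1, height = s$size)
  }))
  row.names(coords) <- NULL

  paths <- csv_path
  if (render) {
    fig_path <- file.path(dir, paste0("alluvial.", format))
    if (format == "png") {
      grDevices::png(fig_path, width = 900, height = 600, type = "cairo")
    } else {
      grDevices::svg(fig_path, width = 9, height = 6)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_alluvial(coords, flows, wl)
    paths <- c(csv_path, fig_path)
  }
  invisible(list(coords = coords, flows = flows, paths = paths))
}

draw_alluvial <- function(coords, flows, wave_order) {
  nw <- length(wave_order)
  xs <- stats::setNames(seq_len(nw), wave_order)
  ymax <- max(coords$y1)
  pal <- grDevices::hcl.colors(max(3L, length(unique(coords$node))), "Dark 3")
  node_col <- stats::setNames(pal[seq_along(unique(coords$node))],
                              unique(coords$node))
  graphics::plot(NULL, xlim = c(0.7, nw + 0.3), ylim = c(0, ymax),
                 axes = FALSE, xlab = "", ylab = "patients",
                 main = "Multimorbidity trajectories")
  graphics::axis(1, at = seq_len(nw), labels = wave_order, lwd = 0)
  graphics::axis(2)

  bw <- 0.08
  # stripe offsets within each box
  off_from <- stats::setNames(rep(0, nrow(coords)),
                              paste(coords$wave, coords$node))
  off_to <- off_from
  ord <- order(match(flows$wave_from, wave_order), flows$node_from, flows$node_to)
  for (i in ord) {
    f <- flows[i, ]
    cf <- coords[coords$wave == f$wave_from & coords$node == f$node_from, ]
    ct <- coords[coords$wave == f$wave_to & coords$node == f$node_to, ]
    kf <- paste(f$wave_from, f$node_from)
    kt <- paste(f$wave_to, f$node_to)
    y0f <- cf$y0 + off_from[kf]; y1f <- y0f + f$count
    y0t <- ct$y0 + off_to[kt]; y1t <- y0t + f$count
    off_from[kf] <- off_from[kf] + f$count
    off_to[kt] <- off_to[kt] + f$count
    xf <- xs[f$wave_from] + bw; xt <- xs[f$wave_to] - bw
    xseq <- seq(xf, xt, length.out = 40)
    ease <- stats::plogis(seq(-4, 4, length.out = 40))
    top <- y1f + (y1t - y1f) * ease
    bot <- y0f + (y0t - y0f) * ease
    graphics::polygon(c(xseq, rev(xseq)), c(top, rev(bot)),
                      col = grDevices::adjustcolor(node_col[f$node_from], 0.35),
                      border = NA)
  }
  for (i in seq_len(nrow(coords))) {
    nd <- coords[i, ]
    graphics::rect(xs[nd$wave] - bw, nd$y0, xs[nd$wave] + bw, nd$y1,
                   col = node_col[nd$node], border = "grey20")
    graphics::text(xs[nd$wave], (nd$y0 + nd$y1) / 2, nd$node, cex = 0.7,
                   srt = 90)
  }
}

#' Read back an exported flows table
#'
#' @param path path to a `flows.csv` written by [export_alluvial()].
#' @return data frame of flows.
#' @export
read_flows <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(wave_from = "character", wave_to = "character"))
}
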