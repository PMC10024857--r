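#' Compose the multi-channel pseudo-fluorescent stack
#'
#' Warps every round's chromogen density map onto the reference grid and
#' assembles one channel per antibody round plus a single counterstain
#' channel (taken from `counterstain_round`), i.e. `N_rounds + 1` channels
#' for an N-round panel. Channels are ordered by staining order (round
#' index), independent of the order the rounds are supplied in. Pixels that
#' leave the field in any round are excluded via the stack's validity mask.
#'
#' @param rounds list of rounds; each element is a list with fields
#'   `round` (integer staining-order index), `marker` (channel name),
#'   `chromogen` ([density_map()]), `counterstain` ([density_map()], the
#'   hematoxylin map of that round), and `transform` (a
#'   [round_transform()] onto the reference grid; `NULL` means identity).
#' @param counterstain_round round index whose hematoxylin map becomes the
#'   counterstain channel (default: the reference, lowest round index).
#' @param counterstain_name channel name for the counterstain.
#'
#' @return An object of class `channel_stack`: named list `channels` of
#'   matrices, `channel_names`, `microns_per_pixel`, logical `valid` mask,
#'   and a `provenance` data frame (round, channel, similarity).
#' @export
compose_stack <- function(rounds, counterstain_round = NULL,
                          counterstain_name = "hematoxylin") {
  stopifnot(is.list(rounds), length(rounds) >= 1)
  idx <- vapply(rounds, function(r) as.integer(r$round), integer(1))
  if (anyDuplicated(idx)) stop("duplicate round indices", call. = FALSE)
  rounds <- rounds[order(idx)]
  idx <- sort(idx)
  markers <- vapply(rounds, function(r) as.character(r$marker), character(1))
  if (anyDuplicated(markers)) stop("duplicate channel names", call. = FALSE)
  if (counterstain_name %in% markers)
    stop("a marker channel may not share the counterstain name", call. = FALSE)
  mpp <- vapply(rounds, function(r) r$chromogen$microns_per_pixel, numeric(1))
  if (max(mpp) - min(mpp) > 1e-9)
    stop("rounds have mismatched microns_per_pixel calibration", call. = FALSE)
  dims <- vapply(rounds, function(r) dim(r$chromogen$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("rounds have mismatched grids", call. = FALSE)
  if (is.null(counterstain_round)) counterstain_round <- idx[1]
  ci <- match(counterstain_round, idx)
  if (is.na(ci)) stop("counterstain_round not among supplied rounds", call. = FALSE)

  valid <- base::matrix(TRUE, dims[1, 1], dims[2, 1])
  channels <- vector("list", length(rounds))
  sims <- rep(NA_real_, length(rounds))
  for (i in seq_along(rounds)) {
    tr <- rounds[[i]]$transform
    if (is.null(tr)) {
      channels[[i]] <- rounds[[i]]$chromogen$pixels
    } else {
      w <- warp(rounds[[i]]$chromogen, tr)
      channels[[i]] <- w$pixels
      valid <- valid & attr(w$pixels, "valid")
      sims[i] <- tr$similarity
    }
  }
  cs <- rounds[[ci]]
  cs_px <- if (is.null(cs$transform)) cs$counterstain$pixels
           else warp(cs$counterstain, cs$transform)$pixels
  channels <- c(channels, list(cs_px))
  names(channels) <- c(markers, counterstain_name)
  channels <- lapply(channels, function(m) { attr(m, "valid") <- NULL; m })
  structure(list(
    channels = channels,
    channel_names = names(channels),
    microns_per_pixel = mpp[1],
    valid = valid,
    provenance = data.frame(round = c(idx, counterstain_round),
                            channel = names(channels),
                            similarity = c(sims, sims[ci]))),
    class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %d channels, %d x %d px (%.3g um/px)\n",
              length(x$channels), d[2], d[1], x$microns_per_pixel))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  cat(sprintf("  valid pixels: %.1f%%\n", 100 * mean(x$valid)))
  invisible(x)
}

#' @rdname compose_stack
#' @param x a `channel_stack`.
#' @param channel channel name.
#' @return `stack_channel()`: that channel as a [density_map()].
#' @export
stack_channel <- function(x, channel) {
  stopifnot(inherits(x, "channel_stack"))
  if (!channel %in% x$channel_names)
    stop(sprintf("channel '%s' not in stack (%s)", channel,
                 paste(x$channel_names, collapse = ", ")), call. = FALSE)
  density_map(x$channels[[channel]], x$microns_per_pixel, stain = channel)
}
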