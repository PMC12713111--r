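CATEGORIES <- c("body", "face", "manmade", "natural")
ANIMACY_MAP <- c(body = "animate", face = "animate",
                 manmade = "inanimate", natural = "inanimate")

#' Build the synthetic 52-object stimulus set
#'
#' Generates 52 base objects: 4 categories (body, face, manmade, natural)
#' with 13 objects each -- 6 stubby (low aspect ratio), 6 spiky (high
#' aspect ratio) and 1 median object whose aspect ratio falls strictly
#' between that category's largest stubby and smallest spiky value (found
#' by rejection sampling). Each base object is rendered both intact
#' (textured) and as a silhouette (uniform 0.2 foreground), for 104
#' stimuli sharing identical masks across renderings. Body and face
#' objects are labeled animate, manmade and natural objects inanimate.
#'
#' @param seed session seed; the whole set is reproducible from it.
#' @param size image side length in pixels.
#' @return an object of class `stimulus_set` with components `meta`
#'   (data frame: `id`, `category`, `animacy`, `shape_class`,
#'   `aspect_ratio`), `masks` (list of 52 logical matrices) and `images`
#'   (`$intact`, `$silhouette`: lists of 52 numeric matrices).
#' @examples
#' \donttest{
#' set <- build_stimulus_set(seed = 1)
#' table(set$meta$category, set$meta$shape_class)
#' }
#' @export
build_stimulus_set <- function(seed = 0L, size = 256L) {
  meta <- data.frame()
  masks <- vector("list", 52L)
  images <- list(intact = vector("list", 52L),
                 silhouette = vector("list", 52L))
  id <- 0L
  for (ci in seq_along(CATEGORIES)) {
    cat_name <- CATEGORIES[ci]
    style <- ci - 1L
    cls <- c(rep("stubby", 6L), rep("spiky", 6L))
    ars <- numeric(12L)
    cat_masks <- vector("list", 13L)
    for (j in 1:12) {
      s <- derive_seed(seed, ci * 100L + j)
      cat_masks[[j]] <- generate_shape(cls[j], style, s, size)
      ars[j] <- compute_aspect_ratio(cat_masks[[j]])
    }
    lo <- max(ars[cls == "stubby"])
    hi <- min(ars[cls == "spiky"])
    # median object: rejection-sample until strictly inside (lo, hi)
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      s <- derive_seed(seed, ci * 100L + 50L + attempt)
      cand <- generate_shape("median", style, s, size)
      ar_med <- compute_aspect_ratio(cand)
      if (ar_med > lo && ar_med < hi) break
      if (attempt > 200L) stop("could not place median aspect ratio for ",
                               cat_name)
    }
    cat_masks[[13L]] <- cand
    for (j in 1:13) {
      id <- id + 1L
      masks[[id]] <- cat_masks[[j]]
      sc <- if (j <= 12) cls[j] else "median"
      meta <- rbind(meta, data.frame(
        id = id, category = cat_name,
        animacy = unname(ANIMACY_MAP[cat_name]),
        shape_class = sc,
        aspect_ratio = if (j <= 12) ars[j] else ar_med))
      tex_seed <- derive_seed(seed, 5000L + id)
      images$intact[[id]] <- render_stimulus(cat_masks[[j]], "intact",
                                             tex_seed, style)
      images$silhouette[[id]] <- render_stimulus(cat_masks[[j]], "silhouette",
                                                 tex_seed, style)
    }
  }
  structure(list(meta = meta, masks = masks, images = images, seed = seed,
                 size = size),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Stimulus set:", nrow(x$meta), "base objects x 2 renderings\n")
  print(table(x$meta$category, x$meta$shape_class))
  invisible(x)
}

#' Retrieve one stimulus record
#'
#' @param set a [build_stimulus_set()] result.
#' @param id base object id (1-52).
#' @param rendering `"intact"` or `"silhouette"`.
#' @return list with `id`, labels, `aspect_ratio`, `mask` and `image`.
#' @export
get_stimulus <- function(set, id, rendering = c("intact", "silhouette")) {
  rendering <- match.arg(rendering)
  m <- set$meta[set$meta$id == id, ]
  if (nrow(m) != 1) stop("unknown stimulus id ", id)
  list(id = id, category = m$category, animacy = m$animacy,
       shape_class = m$shape_class, rendering = rendering,
       aspect_ratio = m$aspect_ratio, mask = set$masks[[id]],
       image = set$images[[rendering]][[id]])
}

# deterministic sub-seed derivation (stays within 32-bit integer range)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k) * 7919) %% 2147483629)
}

#' Write stimulus images to PNG files
#'
#' @param set a stimulus set.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_stimuli <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (rend in c("intact", "silhouette")) {
    for (id in set$meta$id) {
      p <- file.path(dir, sprintf("stim%02d_%s.png", id, rend))
      png::writePNG(set$images[[rend]][[id]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
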