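#' Build a sliding-window fragment grid
#'
#' Tiles an image with a square window of side `window` moved by `stride`
#' pixels. Origins are 0-based `(row, col)` upper-left corners in row-major
#' order; windows lie fully inside the image, so right/bottom margins
#' smaller than the window are not tiled. Evaluation uses stride 16;
#' training uses stride equal to the window size to reduce fragment
#' overlap.
#'
#' @param image_height,image_width image size in pixels.
#' @param window square window side in pixels (presets 48, 96, 192).
#' @param stride step in pixels (>= 1).
#' @return An object of class `fragment_grid` with fields `window`,
#'   `stride`, `origins` (data.frame `row`, `col`), `image_height`,
#'   `image_width`.
#' @export
build_grid <- function(image_height, image_width, window, stride = 16L) {
  image_height <- as.integer(image_height); image_width <- as.integer(image_width)
  window <- as.integer(window); stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  if (window > min(image_height, image_width)) {
    stop("window (", window, " px) larger than image (",
         image_height, " x ", image_width, ")")
  }
  rs <- seq.int(0L, image_height - window, by = stride)
  cs <- seq.int(0L, image_width - window, by = stride)
  structure(
    list(
      window = window, stride = stride,
      origins = data.frame(
        row = rep(rs, each = length(cs)),
        col = rep(cs, times = length(rs))
      ),
      image_height = image_height, image_width = image_width
    ),
    class = "fragment_grid"
  )
}

#' @export
print.fragment_grid <- function(x, ...) {
  cat(sprintf("<fragment_grid> %d windows of %d px, stride %d, on %d x %d\n",
              nrow(x$origins), x$window, x$stride,
              x$image_height, x$image_width))
  invisible(x)
}

same_grid <- function(a, b) {
  a$window == b$window && a$stride == b$stride &&
    a$image_height == b$image_height && a$image_width == b$image_width &&
    nrow(a$origins) == nrow(b$origins) &&
    all(a$origins$row == b$origins$row) && all(a$origins$col == b$origins$col)
}

#' Label fragments by annotated-nucleus presence
#'
#' A fragment is positive (label 1) iff at least one annotated tumor
#' nucleus center -- of either stain class -- falls inside its half-open
#' window `[row, row + w) x [col, col + w)`.
#'
#' @param grid a [build_grid()] result.
#' @param annotations an [annotation_set()].
#' @return Integer vector of 0/1 labels, one per grid origin.
#' @export
label_fragments <- function(grid, annotations) {
  stopifnot(inherits(grid, "fragment_grid"),
            inherits(annotations, "annotation_set"))
  pts <- annotations$points
  n <- nrow(grid$origins)
  if (nrow(pts) == 0L) return(integer(n))
  if (any(pts$x < 0 | pts$x >= grid$image_width |
            pts$y < 0 | pts$y >= grid$image_height)) {
    stop("annotation coordinates outside image bounds")
  }
  w <- grid$window
  inside_r <- outer(grid$origins$row, pts$y,
                    function(r, y) y >= r & y < r + w)
  inside_c <- outer(grid$origins$col, pts$x,
                    function(cc, x) x >= cc & x < cc + w)
  as.integer(rowSums(inside_r & inside_c) > 0)
}

#' Extract one fragment's pixels
#'
#' @param image a [slide_image()] matching the grid's dimensions.
#' @param grid a [build_grid()] result.
#' @param index origin index in `1..nrow(grid$origins)`.
#' @return Integer array `window x window x 3`.
#' @export
extract_fragment <- function(image, grid, index) {
  stopifnot(inherits(image, "slide_image"), inherits(grid, "fragment_grid"))
  if (img_height(image) != grid$image_height ||
        img_width(image) != grid$image_width) {
    stop("image dimensions do not match the grid")
  }
  if (index < 1L || index > nrow(grid$origins)) {
    stop("fragment index ", index, " out of range 1..", nrow(grid$origins))
  }
  r <- grid$origins$row[index]; cc <- grid$origins$col[index]; w <- grid$window
  image$pixels[(r + 1):(r + w), (cc + 1):(cc + w), , drop = FALSE]
}

#' Cache fragment labels as CSV
#'
#' @param grid a `fragment_grid`.
#' @param labels 0/1 vector from [label_fragments()] or a prediction.
#' @param path CSV path with columns `origin_row, origin_col, label`.
#' @return `path` invisibly (write); integer labels (read, checked against
#'   `grid`).
#' @export
write_labels_csv <- function(grid, labels, path) {
  stopifnot(length(labels) == nrow(grid$origins))
  write.csv(
    data.frame(origin_row = grid$origins$row, origin_col = grid$origins$col,
               label = as.integer(labels)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(grid, path) {
  df <- read.csv(path)
  if (nrow(df) != nrow(grid$origins) ||
        !all(df$origin_row == grid$origins$row) ||
        !all(df$origin_col == grid$origins$col)) {
    stop("cached labels do not match the grid")
  }
  as.integer(df$label)
}
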