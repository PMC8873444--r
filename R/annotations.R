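ANNOTATION_LABELS <- c("dab_positive", "hematoxylin_only")

#' Construct a nucleus annotation set
#'
#' Point annotations of tumor nuclei for one slide. Coordinates are 0-based
#' with `x` the column and `y` the row (pixel-center convention); labels are
#' `"dab_positive"` (Ki-67 positive, DAB brown) or `"hematoxylin_only"`
#' (blue counterstain only).
#'
#' @param points data.frame with columns `x`, `y`, `label` (may have 0 rows).
#' @param slide_id character identifier of the owning slide.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(points, slide_id = "slide") {
  if (nrow(points) == 0L) {
    points <- data.frame(x = integer(), y = integer(), label = character())
  }
  stopifnot(all(c("x", "y", "label") %in% names(points)))
  bad <- setdiff(unique(points$label), ANNOTATION_LABELS)
  if (length(bad)) {
    stop("unknown annotation labels: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      slide_id = as.character(slide_id),
      points = data.frame(
        x = as.numeric(points$x), y = as.numeric(points$y),
        label = as.character(points$label)
      )
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set '%s'> %d nuclei (%d DAB-positive, %d hematoxylin-only)\n",
    x$slide_id, nrow(x$points), sum(x$points$label == "dab_positive"),
    sum(x$points$label == "hematoxylin_only")
  ))
  invisible(x)
}

#' Count-based ground-truth proliferation index
#'
#' The proliferation index is the number of Ki-67-positive (DAB-stained)
#' nuclei divided by the total number of annotated tumor nuclei.
#'
#' @param annotations an [annotation_set()].
#' @return An object of class `ground_truth_pi` with fields `n_positive`,
#'   `n_negative` and `pi`.
#' @export
ground_truth_pi <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  n_pos <- sum(annotations$points$label == "dab_positive")
  n_neg <- sum(annotations$points$label == "hematoxylin_only")
  if (n_pos + n_neg == 0L) {
    stop("no annotated nuclei: proliferation index is undefined")
  }
  structure(
    list(n_positive = n_pos, n_negative = n_neg,
         pi = n_pos / (n_pos + n_neg)),
    class = "ground_truth_pi"
  )
}

#' @export
print.ground_truth_pi <- function(x, ...) {
  cat(sprintf("<ground_truth_pi> PI = %.4f (%d positive / %d nuclei)\n",
              x$pi, x$n_positive, x$n_positive + x$n_negative))
  invisible(x)
}

#' Read ImageJ Cell Counter marker XML
#'
#' Parses the marker file written by ImageJ's Cell Counter plug-in. Counter
#' types carry no stain semantics in the file, so a mapping from type number
#' to label is required; types mapped to `"ignored"` are skipped. The file's
#' 1-based coordinates are shifted to the package's 0-based convention.
#'
#' @param path path to a Cell Counter marker XML file.
#' @param class_map named vector/list mapping counter type (as character,
#'   e.g. `"1"`) to `"dab_positive"`, `"hematoxylin_only"` or `"ignored"`.
#' @param slide_id identifier; defaults to the `Image_Filename` element when
#'   present, else the file name.
#' @return An [annotation_set()].
#' @export
read_cellcounter_xml <- function(path, class_map, slide_id = NULL) {
  doc <- xml2::read_xml(path)
  class_map <- unlist(class_map)
  names(class_map) <- as.character(names(class_map))
  fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//Image_Filename"))
  if (is.null(slide_id)) {
    slide_id <- if (!is.na(fname) && nzchar(fname)) {
      tools::file_path_sans_ext(fname)
    } else {
      tools::file_path_sans_ext(basename(path))
    }
  }
  types <- xml2::xml_find_all(doc, ".//Marker_Type")
  xs <- numeric(); ys <- numeric(); labs <- character()
  seen_types <- character()
  for (tnode in types) {
    type <- xml2::xml_text(xml2::xml_find_first(tnode, "./Type"))
    markers <- xml2::xml_find_all(tnode, "./Marker")
    if (length(markers) == 0L) next
    seen_types <- c(seen_types, type)
    if (!type %in% names(class_map)) next
    lab <- class_map[[type]]
    if (identical(lab, "ignored")) next
    mx <- as.numeric(xml2::xml_text(xml2::xml_find_all(markers, "./MarkerX")))
    my <- as.numeric(xml2::xml_text(xml2::xml_find_all(markers, "./MarkerY")))
    xs <- c(xs, mx - 1)            # 1-based file -> 0-based internal
    ys <- c(ys, my - 1)
    labs <- c(labs, rep(lab, length(mx)))
  }
  unmapped <- setdiff(seen_types, names(class_map))
  if (length(unmapped)) {
    stop("unmapped Cell Counter marker types: ",
         paste(sort(unmapped), collapse = ", "),
         " (map them to a label or to \"ignored\")")
  }
  annotation_set(data.frame(x = xs, y = ys, label = labs), slide_id)
}

#' Write an annotation set as Cell Counter marker XML
#'
#' Inverse of [read_cellcounter_xml()]: DAB-positive nuclei become counter
#' type 1 and hematoxylin-only type 2, with 0-based coordinates shifted back
#' to the plug-in's 1-based convention.
#'
#' @param annotations an [annotation_set()].
#' @param path output path.
#' @param image_filename value for the `Image_Filename` element.
#' @return `path`, invisibly.
#' @export
write_cellcounter_xml <- function(annotations, path,
                                  image_filename = paste0(annotations$slide_id, ".png")) {
  stopifnot(inherits(annotations, "annotation_set"))
  doc <- xml2::xml_new_root("CellCounter_Marker_File")
  img <- xml2::xml_add_child(doc, "Image_Properties")
  xml2::xml_add_child(img, "Image_Filename", image_filename)
  md <- xml2::xml_add_child(doc, "Marker_Data")
  for (type in c(1L, 2L)) {
    lab <- ANNOTATION_LABELS[type]
    tnode <- xml2::xml_add_child(md, "Marker_Type")
    xml2::xml_add_child(tnode, "Type", as.character(type))
    pts <- annotations$points[annotations$points$label == lab, , drop = FALSE]
    if (nrow(pts)) {
      for (i in seq_len(nrow(pts))) {
        m <- xml2::xml_add_child(tnode, "Marker")
        xml2::xml_add_child(m, "MarkerX", as.character(pts$x[i] + 1))
        xml2::xml_add_child(m, "MarkerY", as.character(pts$y[i] + 1))
        xml2::xml_add_child(m, "MarkerZ", "1")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read/write the annotation CSV dialect
#'
#' Plain-text alternative to marker XML with header
#' `slide_id,x,y,label` and 0-based coordinates.
#'
#' @param path CSV path.
#' @param slide_id optional filter/identifier; default: taken from the file
#'   (which must then contain exactly one slide).
#' @return An [annotation_set()] (read) or `path` invisibly (write).
#' @export
read_annotation_csv <- function(path, slide_id = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("slide_id", "x", "y", "label") %in% names(df)))
  if (is.null(slide_id)) {
    ids <- unique(df$slide_id)
    if (length(ids) > 1L) {
      stop("annotation CSV contains several slides; pass `slide_id`")
    }
    slide_id <- if (length(ids)) ids else "slide"
  } else {
    df <- df[df$slide_id == slide_id, , drop = FALSE]
  }
  annotation_set(df[, c("x", "y", "label")], slide_id)
}

#' @rdname read_annotation_csv
#' @param annotations an [annotation_set()].
#' @export
write_annotation_csv <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_set"))
  df <- cbind(slide_id = annotations$slide_id, annotations$points)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Randomly partition slides into chunks
#'
#' Uniformly random disjoint partition of a slide collection into `k`
#' chunks of prescribed sizes, as used for k-fold training (three training
#' chunks) plus a held-out testing chunk.
#'
#' @param slide_ids character vector of slide identifiers.
#' @param chunk_sizes integer vector; must sum to `length(slide_ids)`.
#' @param seed integer seed making the partition reproducible.
#' @return An object of class `chunk_partition` with fields `assignment`
#'   (named integer vector, slide id -> chunk in `1..k`), `chunk_sizes`
#'   and `seed`.
#' @export
partition_chunks <- function(slide_ids, chunk_sizes, seed) {
  slide_ids <- as.character(slide_ids)
  chunk_sizes <- as.integer(chunk_sizes)
  if (any(chunk_sizes < 0L)) stop("chunk sizes must be non-negative")
  if (sum(chunk_sizes) != length(slide_ids)) {
    stop("chunk sizes sum to ", sum(chunk_sizes), " but there are ",
         length(slide_ids), " slides")
  }
  if (anyDuplicated(slide_ids)) stop("duplicated slide ids")
  perm <- local_seed(seed, sample(slide_ids))
  chunk_of_perm <- rep(seq_along(chunk_sizes), times = chunk_sizes)
  assignment <- setNames(chunk_of_perm[match(slide_ids, perm)], slide_ids)
  structure(
    list(assignment = assignment, chunk_sizes = chunk_sizes, seed = seed),
    class = "chunk_partition"
  )
}

#' @export
print.chunk_partition <- function(x, ...) {
  cat(sprintf("<chunk_partition> %d slides in %d chunks (%s), seed %d\n",
              length(x$assignment), length(x$chunk_sizes),
              paste(x$chunk_sizes, collapse = "/"), x$seed))
  invisible(x)
}

#' Chunk members of a partition
#'
#' @param partition a [partition_chunks()] result.
#' @param chunk chunk index in `1..k`.
#' @return character vector of slide ids.
#' @export
chunk_slides <- function(partition, chunk) {
  names(partition$assignment)[partition$assignment == chunk]
}

#' Serialize a chunk partition as JSON
#'
#' @param partition a `chunk_partition`.
#' @param path JSON path.
#' @return `path` invisibly (write); a `chunk_partition` (read).
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(
    list(seed = partition$seed, chunk_sizes = partition$chunk_sizes,
         assignment = as.list(partition$assignment)),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(assignment = setNames(as.integer(obj$assignment), names(obj$assignment)),
         chunk_sizes = as.integer(obj$chunk_sizes), seed = as.integer(obj$seed)),
    class = "chunk_partition"
  )
}
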