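ANNOTATION_LABELS <- c("uterus", "tumor")

#' Parse LabelMe-style polygon annotations
#'
#' Reads the `shapes` list of a LabelMe JSON document (fields `label` and
#' `points`) into polygon annotations. Shapes with labels other than
#' `uterus` / `tumor` are excluded with a warning and listed in the
#' `excluded` attribute of the result, never silently dropped.
#'
#' @param json a file path or a JSON string
#' @return list of annotations, each a list with `label` and `vertices`
#'   (n x 2 matrix of 0-based (x = column, y = row) pixel coordinates);
#'   attributes `image_height` / `image_width` when present in the document,
#'   and `excluded` (data frame of shape index + label)
#' @export
parse_labelme <- function(json) {
  txt <- if (length(json) == 1 && !grepl("[{\\[]", json) && file.exists(json))
    paste(readLines(json, warn = FALSE), collapse = "\n") else json
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) stop("malformed LabelMe document: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(doc$shapes))
    stop("malformed LabelMe document: no 'shapes' list")
  anns <- list()
  excluded <- list()
  for (i in seq_along(doc$shapes)) {
    sh <- doc$shapes[[i]]
    if (is.null(sh$label) || is.null(sh$points))
      stop("malformed shape ", i, ": needs 'label' and 'points'")
    if (!sh$label %in% ANNOTATION_LABELS) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(shape = i, label = sh$label, stringsAsFactors = FALSE)
      next
    }
    pts <- tryCatch(
      do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p)[1:2]))),
      error = function(e) stop("malformed shape ", i, ": bad points",
                               call. = FALSE))
    if (nrow(pts) < 3 || anyNA(pts))
      stop("malformed shape ", i, ": a polygon needs >= 3 finite vertices")
    colnames(pts) <- c("x", "y")
    anns[[length(anns) + 1L]] <-
      structure(list(label = sh$label, vertices = pts),
                class = "polygon_annotation")
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(shape = integer(), label = character())
  if (nrow(excluded) > 0)
    warning("excluded ", nrow(excluded), " shape(s) with unknown label(s): ",
            paste(unique(excluded$label), collapse = ", "))
  attr(anns, "excluded") <- excluded
  if (!is.null(doc$imageHeight)) attr(anns, "image_height") <- doc$imageHeight
  if (!is.null(doc$imageWidth)) attr(anns, "image_width") <- doc$imageWidth
  anns
}

# even-odd point-in-polygon, boundary inclusive; vectorized over points
.points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    onseg <- abs(cross) <= eps * (1 + abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onedge <- onedge | onseg
    j <- i
  }
  inside | onedge
}

#' Rasterize polygon annotations into a label mask
#'
#' Polygons are filled under the even-odd rule with the boundary included
#' (a pixel center lying exactly on an edge belongs to the region). Uterus
#' polygons are painted first and tumor polygons after, so a tumor nested
#' inside the uterus outline takes precedence pixel-wise.
#'
#' @param annotations list of annotations from [parse_labelme()]
#' @param shape integer vector `c(rows, cols)` of the target mask
#' @return integer label mask (0 = background, 1 = uterus, 2 = tumor)
#' @export
rasterize_annotations <- function(annotations, shape) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  rows <- shape[1]; cols <- shape[2]
  mask <- matrix(LBL_BG, rows, cols)
  px <- rep(seq_len(cols) - 1, each = rows)   # x = column, 0-based
  py <- rep(seq_len(rows) - 1, times = cols)  # y = row, 0-based
  paint <- function(mask, ann, i, code) {
    v <- ann$vertices
    if (any(v[, 1] < 0 | v[, 1] > cols - 1 | v[, 2] < 0 | v[, 2] > rows - 1))
      stop("polygon ", i, " (", ann$label, ") has vertices outside the image")
    hit <- .points_in_polygon(px, py, v[, 1], v[, 2])
    mask[matrix(hit, rows, cols)] <- code
    mask
  }
  for (i in seq_along(annotations))
    if (annotations[[i]]$label == "uterus")
      mask <- paint(mask, annotations[[i]], i, LBL_UTERUS)
  for (i in seq_along(annotations))
    if (annotations[[i]]$label == "tumor")
      mask <- paint(mask, annotations[[i]], i, LBL_TUMOR)
  storage.mode(mask) <- "integer"
  mask
}

#' Patient-level train / validation / test split
#'
#' Partition sizes follow the largest-remainder apportionment of `ratios`
#' (for 117 patients and 6:1:3 this gives 70 / 12 / 35). The split is by
#' patient, never by slice, so all slices of one patient share a partition.
#'
#' @param patient_ids character vector of unique patient ids
#' @param ratios length-3 non-negative weights for train / validation / test
#' @param seed integer; the split is a deterministic function of it
#' @return list with `train`, `validation`, `test` character vectors
#' @export
split_dataset <- function(patient_ids, ratios = c(6, 1, 3), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0), sum(ratios) > 0)
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  n <- length(patient_ids)
  if (n < sum(ratios > 0))
    stop("too few patients (", n, ") for ", sum(ratios > 0),
         " non-empty partitions")
  quota <- n * ratios / sum(ratios)
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(-(quota - sizes), seq_along(quota))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  set.seed(seed)
  shuffled <- sample(patient_ids)
  cuts <- cumsum(sizes)
  structure(list(
    train = sort(shuffled[seq_len(sizes[1])]),
    validation = sort(shuffled[seq_len(sizes[2]) + cuts[1]]),
    test = sort(shuffled[seq_len(sizes[3]) + cuts[2]])
  ), class = "dataset_split")
}
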