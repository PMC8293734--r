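#' Construct an image dataset
#'
#' Container used throughout the package: a list of H x W x 3 pixel arrays
#' in \[0, 1\] plus a metadata data.frame with one row per image
#' (`file`, `label` in {"benign","malignant"}, `y` integer 0/1,
#' `patient_id`, `magnification`, optional extras).
#'
#' @param images list of H x W x 3 numeric arrays with values in \[0, 1\].
#' @param meta data.frame with columns `file`, `label`, `patient_id`,
#'   `magnification`.
#' @return An `image_dataset` with a `patient_index` (patient_id ->
#'   image indices) and class counts.
#' @export
image_dataset <- function(images, meta) {
  stopifnot(is.list(images), nrow(meta) == length(images),
            all(c("file", "label", "patient_id", "magnification") %in% names(meta)),
            all(meta$label %in% c("benign", "malignant")),
            all(nzchar(meta$patient_id)))
  meta$y <- ifelse(meta$label == "malignant", 1L, 0L)
  structure(list(
    images = images,
    meta = meta,
    class_counts = table(meta$label),
    patient_index = split(seq_len(nrow(meta)), meta$patient_id)
  ), class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d images, %d patients (%s)\n",
              length(x$images), length(x$patient_index),
              paste(names(x$class_counts), x$class_counts,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
length.image_dataset <- function(x) length(x$images)

# Subset a dataset by image indices, keeping metadata aligned.
dataset_subset <- function(dataset, idx) {
  image_dataset(dataset$images[idx], dataset$meta[idx, , drop = FALSE])
}

#' Parse a BreakHis-style image filename
#'
#' Grammar: `BIOPSY_CLASS_SUBTYPE-YEAR-SLIDE-MAG-SEQ.EXT`, e.g.
#' `SOB_B_TA-14-4659-40-001.png`. CLASS `B` maps to benign and `M` to
#' malignant; the patient identifier is `YEAR-SLIDE`; MAG is the
#' magnification factor.
#'
#' @param name filename (with or without directory part).
#' @return `list(label=, patient_id=, magnification=)`.
#' @export
parse_filename <- function(name) {
  base <- basename(name)
  m <- regmatches(base, regexec(
    "^[A-Za-z]+_([BM])_[A-Za-z]+-([0-9]+)-([0-9A-Za-z]+)-([0-9]+)-([0-9]+)\\.(png|jpg|jpeg|tif|tiff)$",
    base, ignore.case = FALSE))[[1]]
  if (length(m) == 0)
    stop("filename does not match the BIOPSY_CLASS_SUBTYPE-YEAR-SLIDE-MAG-SEQ grammar: ",
         base)
  list(label = if (m[2] == "B") "benign" else "malignant",
       patient_id = paste0(m[3], "-", m[4]),
       magnification = as.integer(m[5]))
}

#' Read a two-class image folder into a dataset
#'
#' Recursively collects PNG/JPEG/TIFF files whose names follow the grammar
#' of [parse_filename()] (flat or nested layout), decodes them, resizes to
#' `target_size` with bilinear interpolation, and scales pixels to
#' \[0, 1\]. Files with non-conforming names or decode failures are skipped
#' with a warning. Files are processed in sorted-name order, so re-reading
#' a folder always yields an identical dataset.
#'
#' @param root folder to read.
#' @param target_size integer `c(height, width)`; default `c(210, 210)`.
#' @return an `image_dataset`.
#' @export
read_image_folder <- function(root, target_size = c(210L, 210L)) {
  stopifnot(dir.exists(root), length(target_size) == 2)
  files <- sort(list.files(root, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                           recursive = TRUE, full.names = TRUE,
                           ignore.case = TRUE))
  all_names <- sort(list.files(root, recursive = TRUE))
  if (length(all_names) == 0) stop("empty folder: ", root)
  images <- list(); rows <- list()
  for (f in files) {
    info <- tryCatch(parse_filename(f), error = function(e) NULL)
    if (is.null(info)) {
      warning("skipping unparsable filename: ", basename(f), call. = FALSE)
      next
    }
    px <- tryCatch(load_pixels(f, target_size), error = function(e) {
      warning("skipping unreadable file ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(px)) next
    images[[length(images) + 1L]] <- px
    rows[[length(rows) + 1L]] <- data.frame(
      file = basename(f), label = info$label, patient_id = info$patient_id,
      magnification = info$magnification, stringsAsFactors = FALSE)
  }
  for (nm in setdiff(basename(all_names), vapply(rows, `[[`, "", "file"))) {
    if (!grepl("\\.(png|jpg|jpeg|tif|tiff)$", nm, ignore.case = TRUE))
      warning("skipping unparsable filename: ", nm, call. = FALSE)
  }
  if (length(images) == 0) stop("no readable images in ", root)
  image_dataset(images, do.call(rbind, rows))
}

# Decode one image file to an H x W x 3 array in [0,1], bilinear-resized.
load_pixels <- function(path, target_size) {
  img <- EBImage::readImage(path)   # EBImage stores x (width) first
  d <- dim(img)
  if (length(d) == 2) {
    img <- EBImage::Image(array(rep(as.numeric(img), 3), dim = c(d, 3)),
                          colormode = "Color")
  } else if (d[3] > 3) {
    img <- img[, , 1:3]             # drop alpha
  }
  img <- EBImage::resize(img, w = target_size[2], h = target_size[1],
                         filter = "bilinear")
  px <- aperm(as.array(img), c(2L, 1L, 3L))   # to row, column, channel
  px[px < 0] <- 0; px[px > 1] <- 1
  px
}

#' Patient-wise train/test split
#'
#' Shuffles the patients with the given seed, then assigns whole patients
#' greedily to the training set until its image count first reaches
#' `train_fraction` of all images; the remaining patients form the test
#' set. No patient ever appears in both sets. If the greedy rule would
#' consume every patient, the last one is held back so the test set is
#' never empty.
#'
#' @param dataset an `image_dataset` with at least 2 patients.
#' @param train_fraction target fraction of images in the training set.
#' @param seed integer seed for the patient shuffle.
#' @return `list(train=, test=)` of `image_dataset`s.
#' @export
split_patientwise <- function(dataset, train_fraction = 0.7, seed = 0L) {
  stopifnot(inherits(dataset, "image_dataset"),
            train_fraction > 0, train_fraction < 1)
  patients <- names(dataset$patient_index)
  if (length(patients) < 2) stop("patient-wise split needs at least 2 patients")
  ord <- with_seed(seed, sample(patients))
  n_total <- length(dataset$images)
  target <- train_fraction * n_total
  train_patients <- character(0); n_train <- 0L
  for (p in ord) {
    if (n_train >= target) break
    train_patients <- c(train_patients, p)
    n_train <- n_train + length(dataset$patient_index[[p]])
  }
  if (length(train_patients) == length(patients))
    train_patients <- train_patients[-length(train_patients)]
  train_idx <- sort(unlist(dataset$patient_index[train_patients],
                           use.names = FALSE))
  test_idx <- setdiff(seq_len(n_total), train_idx)
  list(train = dataset_subset(dataset, train_idx),
       test = dataset_subset(dataset, test_idx))
}

#' Generate a seeded synthetic two-class histology-like dataset
#'
#' Emulates the structure of a benign/malignant histopathology collection
#' with multiple patients, as a fully offline test bed. Benign images show
#' a few large pale blobs on a light pink background (sparse, regular
#' tissue); malignant images show many small dark-purple blobs with higher
#' count variance on a slightly darker background (dense, irregular
#' nuclei). Each image receives a random overall luminance factor
#' (emulating stain/illumination variation, and ensuring the classes are
#' not separable by raw brightness alone) plus Gaussian pixel noise, and
#' values are clipped to \[0, 1\]. Images are assigned round-robin to synthetic patients, the
#' patients split evenly between the classes, and filenames follow the
#' grammar of [parse_filename()] so a written folder round-trips through
#' [read_image_folder()].
#'
#' @param n_per_class images per class.
#' @param image_size square image side in pixels.
#' @param n_patients number of synthetic patients (>= 2; split between
#'   classes).
#' @param seed integer seed; identical seeds give bitwise-identical pixels.
#' @param benign_mean_blobs,malignant_mean_blobs mean blob counts
#'   (defaults 6 and 25).
#' @param noise_sd standard deviation of the additive pixel noise.
#' @return an `image_dataset`; `meta$blob_count` logs the number of blobs
#'   drawn in each image.
#' @export
generate_synthetic_dataset <- function(n_per_class = 100L, image_size = 32L,
                                       n_patients = 4L, seed = 0L,
                                       benign_mean_blobs = 6,
                                       malignant_mean_blobs = 25,
                                       noise_sd = 0.02) {
  stopifnot(n_per_class >= 1, image_size >= 8, n_patients >= 2)
  n_benign_pat <- max(1L, n_patients %/% 2L)
  n_malig_pat <- n_patients - n_benign_pat
  pat_ids <- function(cls, n) sprintf("%d-%04d", 14L,
                                      if (cls == "benign") 1000L + seq_len(n)
                                      else 2000L + seq_len(n))
  with_seed(seed, {
    images <- list(); rows <- list()
    seq_by_patient <- new.env(parent = emptyenv())
    for (cls in c("benign", "malignant")) {
      pats <- if (cls == "benign") pat_ids(cls, n_benign_pat)
              else pat_ids(cls, n_malig_pat)
      for (i in seq_len(n_per_class)) {
        pid <- pats[((i - 1L) %% length(pats)) + 1L]
        sq <- (get0(pid, envir = seq_by_patient, ifnotfound = 0L)) + 1L
        assign(pid, sq, envir = seq_by_patient)
        im <- draw_synthetic_image(cls, image_size, benign_mean_blobs,
                                   malignant_mean_blobs, noise_sd)
        images[[length(images) + 1L]] <- im$pixels
        rows[[length(rows) + 1L]] <- data.frame(
          file = sprintf("SOB_%s_%s-%s-40-%03d.png",
                         if (cls == "benign") "B" else "M",
                         if (cls == "benign") "TA" else "DC", pid, sq),
          label = cls, patient_id = pid, magnification = 40L,
          blob_count = im$n_blobs, stringsAsFactors = FALSE)
      }
    }
    image_dataset(images, do.call(rbind, rows))
  })
}

# One synthetic image: background + blobs + noise, clipped to [0,1].
draw_synthetic_image <- function(cls, S, benign_mu, malignant_mu, noise_sd) {
  xg <- matrix(rep(seq_len(S), each = S), nrow = S)    # column coordinate
  yg <- matrix(rep(seq_len(S), times = S), nrow = S)   # row coordinate
  img <- array(0, dim = c(S, S, 3))
  if (cls == "benign") {
    bg <- c(0.93, 0.78, 0.86) + rnorm(3, 0, 0.02)
    n_blobs <- max(1L, stats::rpois(1, benign_mu))
    radius_rng <- c(S / 8, S / 5)
    blob_col <- function() c(0.98, 0.93, 0.96) + rnorm(3, 0, 0.01)
  } else {
    bg <- c(0.82, 0.62, 0.78) + rnorm(3, 0, 0.02)
    # negative binomial: over-dispersed counts (higher variance than benign)
    n_blobs <- max(3L, stats::rnbinom(1, size = 6, mu = malignant_mu))
    radius_rng <- c(S / 20, S / 10)
    blob_col <- function() c(0.42, 0.18, 0.50) + rnorm(3, 0, 0.04)
  }
  for (ch in 1:3) img[, , ch] <- bg[ch]
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, 1, S); cy <- runif(1, 1, S)
    r <- runif(1, radius_rng[1], radius_rng[2])
    col <- blob_col()
    mask <- (xg - cx)^2 + (yg - cy)^2 <= r^2
    alpha <- 0.85
    for (ch in 1:3)
      img[, , ch][mask] <- (1 - alpha) * img[, , ch][mask] + alpha * col[ch]
  }
  # per-image illumination jitter (stain/exposure variation): scales all
  # channels alike, so raw mean brightness alone is an unreliable cue
  img <- img * runif(1, 0.70, 1.20)
  img <- img + array(rnorm(length(img), 0, noise_sd), dim = dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  list(pixels = img, n_blobs = n_blobs)
}

#' Write a dataset to an image folder
#'
#' Writes each image as an 8-bit PNG named by `meta$file`, producing a
#' folder that [read_image_folder()] can ingest (labels, patients and
#' counts round-trip exactly; pixels up to 8-bit quantization).
#'
#' @param dataset an `image_dataset`.
#' @param path output folder (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset_folder <- function(dataset, path) {
  stopifnot(inherits(dataset, "image_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    png::writePNG(dataset$images[[i]],
                  target = file.path(path, dataset$meta$file[i]))
  }
  invisible(path)
}
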