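# Readers and writers for the pipeline's tab-separated exchange formats.
# All writers emit headered TSV with a stable column order; gzip input is
# handled transparently by R's connection layer.

write_tsv <- function(df, path) {
  utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

read_tsv <- function(path, what, cols = NULL, colClasses = NA) {
  if (!file.exists(path)) {
    stop_input("%s file not found: %s", what, path)
  }
  df <- utils::read.table(
    path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = colClasses, check.names = FALSE
  )
  if (!is.null(cols)) {
    check_columns(df, cols, what)
  }
  df
}

#' Read per-base depth profiles from samtools-depth-style TSV
#'
#' Parses a 3-column tab-separated file (`genome_id`, 1-based position,
#' integer depth; no header), plain or gzip-compressed. The sparse dialect
#' is accepted: positions absent from the file are depth 0. Genome lengths
#' come from the `lengths` sidecar when given, otherwise each genome's
#' length is inferred as its maximum observed position.
#'
#' @param path Path to the depth TSV (optionally `.gz`).
#' @param sample_id Sample identifier stamped on the returned profiles;
#'   defaults to the file name without extensions.
#' @param lengths Optional named vector of genome lengths (bp).
#' @return A list of [depth_profile()] objects, one per genome.
#' @export
read_depth_tsv <- function(path, sample_id = NULL, lengths = NULL) {
  if (!file.exists(path)) {
    stop_input("depth file not found: %s", path)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.gz$", "", basename(path))
    sample_id <- sub("\\.(tsv|txt|depth)$", "", sample_id)
  }
  df <- tryCatch(
    utils::read.table(
      path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
      colClasses = c("character", "numeric", "numeric"),
      col.names = c("genome_id", "pos", "depth")
    ),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame(
          genome_id = character(), pos = numeric(), depth = numeric(),
          stringsAsFactors = FALSE
        ))
      }
      stop_input("cannot parse depth file %s: %s", path, conditionMessage(e))
    }
  )
  bad <- which(
    is.na(df$pos) | is.na(df$depth) | df$pos < 1 |
      df$pos != floor(df$pos) | df$depth < 0 | df$depth != floor(df$depth)
  )
  if (length(bad) > 0) {
    stop_input(
      "invalid position/depth in %s at line %d", path, bad[1]
    )
  }
  genome_ids <- unique(c(df$genome_id, names(lengths)))
  lapply(stats::setNames(genome_ids, genome_ids), function(g) {
    sub <- df[df$genome_id == g, ]
    L <- if (!is.null(lengths) && g %in% names(lengths)) {
      lengths[[g]]
    } else if (nrow(sub) > 0) {
      max(sub$pos)
    } else {
      stop_input("genome %s has no observed positions and no declared length", g)
    }
    if (nrow(sub) > 0 && max(sub$pos) > L) {
      stop_input(
        "genome %s has positions beyond its declared length %d", g, L
      )
    }
    d <- numeric(L)
    d[sub$pos] <- sub$depth
    depth_profile(g, sample_id, d)
  })
}

#' Write depth profiles as samtools-depth-style TSV
#'
#' @param profiles List of [depth_profile()] objects (one sample).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param sparse Omit zero-depth positions? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(profiles, path, sparse = TRUE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    keep <- if (sparse) which(p$depths > 0) else seq_along(p$depths)
    if (length(keep) > 0) {
      utils::write.table(
        data.frame(p$genome_id, keep, p$depths[keep]),
        con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
      )
    }
  }
  invisible(path)
}

#' Read and write pipeline tables
#'
#' Headered TSV readers/writers for the pipeline's exchange formats:
#' coverage summaries (`sample_id`, `genome_id`, `q2q3_mean_depth`,
#' `breadth`, `detected`), clade maps (`genome_id`, `clade_id`), site maps
#' (`sample_id`, `site`), genome records, long-format function tables
#' (`genome_id`, `accession`, `count`), square ANI matrices (genome ids as
#' header row and first column), and flattened module definitions
#' (`module_id`, `step_index`, comma-separated `alternatives`).
#'
#' @param path File path.
#' @param df,ani,modules Object to write.
#' @return Readers return a data.frame (or for
#'   [read_ani_tsv()] a named matrix, for [read_modules_tsv()] a list of
#'   [module_definition()]); writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_coverage_tsv <- function(path) {
  df <- read_tsv(
    path, "coverage summary",
    c("sample_id", "genome_id", "q2q3_mean_depth", "breadth", "detected"),
    colClasses = c(
      sample_id = "character", genome_id = "character",
      q2q3_mean_depth = "numeric", breadth = "numeric", detected = "logical"
    )
  )
  df
}

#' @rdname pipeline_io
#' @export
write_coverage_tsv <- function(df, path) {
  check_columns(
    df, c("sample_id", "genome_id", "q2q3_mean_depth", "breadth", "detected"),
    "coverage summary"
  )
  write_tsv(
    df[c("sample_id", "genome_id", "q2q3_mean_depth", "breadth", "detected")],
    path
  )
}

#' @rdname pipeline_io
#' @export
read_clade_map_tsv <- function(path) {
  read_tsv(path, "clade map", c("genome_id", "clade_id"), "character")
}

#' @rdname pipeline_io
#' @export
read_site_map_tsv <- function(path) {
  df <- read_tsv(path, "site map", c("sample_id", "site"), "character")
  bad <- setdiff(unique(df$site), oral_sites())
  if (length(bad) > 0) {
    stop_input(
      "unknown site code(s) in %s: %s (expected one of %s)",
      path, paste(bad, collapse = ", "), paste(oral_sites(), collapse = ", ")
    )
  }
  df
}

#' @rdname pipeline_io
#' @export
read_genome_records_tsv <- function(path) {
  read_tsv(
    path, "genome record table",
    c("genome_id", "completeness", "contamination")
  )
}

#' @rdname pipeline_io
#' @export
read_function_table_tsv <- function(path) {
  read_tsv(path, "function table", c("genome_id", "accession", "count"))
}

#' @rdname pipeline_io
#' @export
read_ani_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_input("ANI file not found: %s", path)
  }
  df <- utils::read.table(
    path, sep = "\t", header = TRUE, row.names = 1, check.names = FALSE
  )
  as.matrix(df)
}

#' @rdname pipeline_io
#' @export
write_ani_tsv <- function(ani, path) {
  df <- data.frame(
    genome_id = rownames(ani), as.data.frame(ani), check.names = FALSE
  )
  write_tsv(df, path)
}

#' @rdname pipeline_io
#' @export
read_modules_tsv <- function(path) {
  df <- read_tsv(
    path, "module definitions", c("module_id", "step_index", "alternatives")
  )
  lapply(split(df, df$module_id), function(sub) {
    sub <- sub[order(sub$step_index), ]
    module_definition(
      sub$module_id[1],
      lapply(strsplit(as.character(sub$alternatives), ","), trimws)
    )
  })
}

#' @rdname pipeline_io
#' @export
write_modules_tsv <- function(modules, path) {
  rows <- do.call(rbind, lapply(modules, function(m) {
    data.frame(
      module_id = m$module_id,
      step_index = seq_along(m$steps),
      alternatives = vapply(m$steps, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  write_tsv(rows, path)
}
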