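# Session-bundle persistence: an open on-disk layout (JSON metadata, CSV
# spike/waveform tables, CSV or flat binary LFP arrays with a JSON sidecar).

#' Write a session bundle
#'
#' Serializes a session to a directory: `metadata.json` (ids, genotype,
#' sampling rates, channel and unit tables), one LFP array per channel
#' (either a one-column CSV of microvolts or a flat little-endian binary file
#' with a JSON sidecar recording dtype and length; `float64` round-trips
#' bit-exactly, `float32` halves the size), `spikes.csv` (unit_id, time_s),
#' `waveforms.csv` (unit_id, sample_index, uv), and a `manifest.json` listing
#' files with MD5 checksums.
#'
#' @param session A [lfp_session()].
#' @param path Target directory (created if needed).
#' @param mode `"binary"` or `"csv"` for the LFP arrays.
#' @param dtype Binary sample type, `"float64"` (default) or `"float32"`.
#' @return The manifest, invisibly (list with `files` and `md5`).
#' @export
write_bundle <- function(session, path, mode = c("binary", "csv"),
                         dtype = c("float64", "float32")) {
  mode <- match.arg(mode)
  dtype <- match.arg(dtype)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  channels <- purrr::map(session$lfp, function(tr) {
    stem <- sprintf("lfp_%s", tr$channel_id)
    if (mode == "binary") {
      fname <- paste0(stem, ".bin")
      con <- file(file.path(path, fname), "wb")
      writeBin(as.numeric(tr$samples), con,
               size = if (dtype == "float32") 4L else 8L, endian = "little")
      close(con)
      sidecar <- paste0(stem, ".json")
      jsonlite::write_json(
        list(dtype = dtype, endian = "little",
             n_samples = length(tr$samples), units = "uV"),
        file.path(path, sidecar), auto_unbox = TRUE)
      files <<- c(files, fname, sidecar)
    } else {
      fname <- paste0(stem, ".csv")
      utils::write.csv(data.frame(uv = tr$samples),
                       file.path(path, fname), row.names = FALSE)
      files <<- c(files, fname)
    }
    list(channel_id = tr$channel_id, file = fname, mode = mode,
         n_samples = length(tr$samples))
  })

  spikes <- purrr::map_dfr(session$units, function(u) {
    tibble::tibble(unit_id = u$unit_id,
                   time_s = sprintf("%.17g", u$spike_times))
  })
  if (nrow(spikes) == 0L) {
    spikes <- tibble::tibble(unit_id = character(), time_s = character())
  }
  utils::write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)

  waveforms <- purrr::map_dfr(session$units, function(u) {
    if (is.null(u$mean_waveform)) return(tibble::tibble())
    wf <- u$mean_waveform
    if (is.matrix(wf)) {
      purrr::map_dfr(seq_len(nrow(wf)), function(ch) {
        tibble::tibble(unit_id = u$unit_id, channel = ch,
                       sample_index = seq_len(ncol(wf)), uv = wf[ch, ])
      })
    } else {
      tibble::tibble(unit_id = u$unit_id, channel = 1L,
                     sample_index = seq_along(wf), uv = wf)
    }
  })
  if (nrow(waveforms) == 0L) {
    waveforms <- tibble::tibble(unit_id = character(), channel = integer(),
                                sample_index = integer(), uv = numeric())
  }
  utils::write.csv(waveforms, file.path(path, "waveforms.csv"),
                   row.names = FALSE)

  meta <- list(
    session_id = session$session_id,
    animal_id = session$animal_id,
    genotype = session$genotype,
    fs = if (length(session$lfp) > 0L) session$lfp[[1]]$fs else NA,
    channels = channels,
    units = purrr::map(session$units, function(u) {
      list(unit_id = u$unit_id, waveform_fs = u$waveform_fs,
           layer = u$layer, cell_class = u$cell_class,
           n_spikes = length(u$spike_times))
    })
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "spikes.csv", "waveforms.csv", "metadata.json")
  manifest <- list(
    files = files,
    md5 = as.list(tools::md5sum(file.path(path, files)))
  )
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a session bundle
#'
#' Reconstructs a [lfp_session()] from a directory written by
#' [write_bundle()]. Missing or inconsistent files raise an error naming the
#' file.
#'
#' @param path Bundle directory.
#' @return A [lfp_session()].
#' @export
read_bundle <- function(path) {
  need <- function(fname) {
    fp <- file.path(path, fname)
    if (!file.exists(fp)) {
      stop(sprintf("bundle is missing required file: %s", fname),
           call. = FALSE)
    }
    fp
  }
  meta <- jsonlite::read_json(need("metadata.json"))
  traces <- purrr::map(meta$channels, function(ch) {
    fp <- need(ch$file)
    samples <- if (identical(ch$mode, "binary")) {
      sidecar <- jsonlite::read_json(
        need(sub("\\.bin$", ".json", ch$file)))
      con <- file(fp, "rb")
      on.exit(close(con))
      readBin(con, what = "numeric", n = sidecar$n_samples,
              size = if (identical(sidecar$dtype, "float32")) 4L else 8L,
              endian = "little")
    } else {
      utils::read.csv(fp)$uv
    }
    if (length(samples) != ch$n_samples) {
      stop(sprintf("corrupt LFP array %s: %d samples on disk, %d declared",
                   ch$file, length(samples), ch$n_samples), call. = FALSE)
    }
    lfp_trace(samples, fs = meta$fs, channel_id = ch$channel_id,
              session_id = meta$session_id)
  })
  spikes <- utils::read.csv(need("spikes.csv"),
                            colClasses = c("character", "numeric"))
  waveforms <- utils::read.csv(need("waveforms.csv"))
  declared <- vapply(meta$units, function(u) u$unit_id, character(1))
  extra <- setdiff(unique(spikes$unit_id), declared)
  if (length(extra) > 0L) {
    stop(sprintf("spikes.csv refers to unit(s) absent from metadata.json: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  units <- purrr::map(meta$units, function(u) {
    st <- spikes$time_s[spikes$unit_id == u$unit_id]
    wf_rows <- waveforms[waveforms$unit_id == u$unit_id, , drop = FALSE]
    wf <- NULL
    if (nrow(wf_rows) > 0L) {
      chans <- sort(unique(wf_rows$channel))
      if (length(chans) == 1L) {
        wf <- wf_rows$uv[order(wf_rows$sample_index)]
      } else {
        wf <- t(vapply(chans, function(ch) {
          r <- wf_rows[wf_rows$channel == ch, ]
          r$uv[order(r$sample_index)]
        }, numeric(max(wf_rows$sample_index))))
      }
    }
    spike_unit(u$unit_id, st, mean_waveform = wf,
               waveform_fs = u$waveform_fs, layer = u$layer,
               cell_class = u$cell_class)
  })
  lfp_session(traces, units = units, animal_id = meta$animal_id,
              genotype = meta$genotype, session_id = meta$session_id)
}

#' Write / read an analysis configuration as JSON
#'
#' @param cfg An [analysis_config()].
#' @param path JSON file path.
#' @return `write_analysis_config` returns `path` invisibly;
#'   `read_analysis_config` returns an [analysis_config()].
#' @export
write_analysis_config <- function(cfg, path) {
  flat <- unclass(cfg)
  flat$band_specs <- purrr::map(flat$band_specs, unclass)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- purrr::map(raw$band_specs, function(b) {
    band_spec(b$stop_lo, b$pass_lo, b$pass_hi, b$stop_hi, name = b$name)
  })
  raw$band_specs <- NULL
  do.call(analysis_config, c(raw, list(band_specs = specs)))
}
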