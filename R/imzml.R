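#' Write a datacube as continuous-mode imzML (+ ibd)
#'
#' Emits the standard mass-spectrometry-imaging interchange pair: an XML
#' index (`.imzML`) and a binary data file (`.ibd`) holding one shared m/z
#' array (the bin centers, 64-bit float) followed by one full-length
#' intensity array per pixel (64-bit float, so counts round-trip exactly).
#' Pixels are written row-major; imzML positions are 1-based with x = column
#' and y = row, origin top-left.
#'
#' @param image A [spectral_image()].
#' @param path Output path ending in `.imzML`; the `.ibd` is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(image, path) {
  stopifnot(inherits(image, "spectral_image"))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE))
    path <- paste0(path, ".imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

  ax <- image$axis
  mzs <- bin_centers(ax)
  npx <- image$nx * image$ny
  n <- ax$n_bins

  uuid_bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  uuid_str <- format_uuid(uuid_bytes)

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes, con)
  writeBin(as.numeric(mzs), con, size = 8, endian = "little")
  mz_offset <- 16
  mz_bytes <- 8 * n
  int_offsets <- mz_offset + mz_bytes + (seq_len(npx) - 1) * 8 * n
  dense <- as.matrix(image$counts)  # npx x n; small images only
  for (p in seq_len(npx))
    writeBin(as.numeric(dense[p, ]), con, size = 8, endian = "little")

  pol_param <- if (image$polarity > 0)
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'

  head <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="2">
    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
    <cv id="IMS" fullName="Imaging MS Ontology" uri="https://ms-imaging.org/wp-content/uploads/2009/08/imagingMS.obo"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>
      %s
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="2">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="simslipid" version="0.1.0"/>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1"/>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="simslipid_export">
      <processingMethod order="0" softwareRef="simslipid">
        <cvParam cvRef="MS" accession="MS:1000530" name="file format conversion" value=""/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run defaultInstrumentConfigurationRef="IC1" id="run1">
    <spectrumList count="%d" defaultDataProcessingRef="simslipid_export">
', uuid_str, pol_param, image$nx, image$ny, npx)

  spectra <- character(npx)
  for (p in seq_len(npx)) {
    row <- ((p - 1L) %/% image$nx) + 1L
    col <- ((p - 1L) %% image$nx) + 1L
    spectra[p] <- sprintf(
'      <spectrum defaultArrayLength="%d" id="spectrum=%d" index="%d">
        %s
        <scanList count="1">
          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>
          <scan>
            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>
            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>
', n, p, p, pol_param, col, row, n, mz_bytes, mz_offset, n, mz_bytes,
      int_offsets[p])
  }

  writeLines(c(head, spectra,
               "    </spectrumList>\n  </run>\n</mzML>"),
             path, sep = "")
  invisible(path)
}

format_uuid <- function(bytes) {
  h <- toupper(paste(format(bytes), collapse = ""))
  paste(substr(h, 1, 8), substr(h, 9, 12), substr(h, 13, 16),
        substr(h, 17, 20), substr(h, 21, 32), sep = "-")
}

#' Read a continuous-mode imzML datacube
#'
#' Reads the XML index and the external binary arrays and reconstructs the
#' [spectral_image()]. Continuous files with a shared uniformly spaced m/z
#' array map directly onto a [mass_axis()] (stored m/z values are taken as
#' bin centers); processed-mode files (per-spectrum m/z arrays) are rebinned
#' onto `axis` via [bin_events()]. Pixels missing from the file are left as
#' zero spectra with a warning.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @param axis Optional [mass_axis()]; required for processed mode, and
#'   validated against the file in continuous mode.
#' @return A `spectral_image`.
#' @export
read_imzml <- function(path, axis = NULL) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing ibd file: ", ibd_path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  acc_of <- function(node) xml2::xml_attr(xml2::xml_find_all(node, ".//cvParam"),
                                          "accession")
  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  fc_acc <- acc_of(fc)
  continuous <- "IMS:1000030" %in% fc_acc
  polarity <- if ("MS:1000129" %in% fc_acc) -1L else 1L

  # resolve referenceable param groups: id -> accession vector
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  group_acc <- stats::setNames(
    lapply(groups, acc_of),
    xml2::xml_attr(groups, "id")
  )

  cv_value <- function(node, accession) {
    p <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']",
                                            accession))
    xml2::xml_attr(p, "value")
  }

  spectra <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (!length(spectra)) stop("no spectra in ", path)

  parse_bda <- function(sp) {
    out <- list()
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      own <- acc_of(bda)
      ref <- xml2::xml_attr(
        xml2::xml_find_first(bda, ".//referenceableParamGroupRef"), "ref")
      all_acc <- c(own, if (!is.na(ref)) group_acc[[ref]])
      kind <- if ("MS:1000514" %in% all_acc) "mz"
              else if ("MS:1000515" %in% all_acc) "intensity"
              else next
      size <- if ("MS:1000523" %in% all_acc) 8L
              else if ("MS:1000521" %in% all_acc) 4L
              else stop("unsupported binary data type in ", path)
      out[[kind]] <- list(
        offset = as.numeric(cv_value(bda, "IMS:1000102")),
        length = as.integer(cv_value(bda, "IMS:1000103")),
        size = size
      )
    }
    out
  }

  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(a) {
    seek(con, where = a$offset, origin = "start")
    readBin(con, what = "numeric", n = a$length, size = a$size,
            endian = "little")
  }

  xs <- integer(length(spectra)); ys <- integer(length(spectra))
  recs <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    xs[i] <- as.integer(cv_value(sp, "IMS:1000050"))
    ys[i] <- as.integer(cv_value(sp, "IMS:1000051"))
    recs[[i]] <- parse_bda(sp)
  }
  nx <- max(xs); ny <- max(ys)
  ss <- xml2::xml_find_first(doc, ".//scanSettings")
  if (!inherits(ss, "xml_missing")) {
    v <- suppressWarnings(as.integer(cv_value(ss, "IMS:1000042")))
    if (!is.na(v)) nx <- max(nx, v)
    v <- suppressWarnings(as.integer(cv_value(ss, "IMS:1000043")))
    if (!is.na(v)) ny <- max(ny, v)
  }

  if (continuous) {
    mzs <- read_array(recs[[1]]$mz)
    w <- diff(mzs)
    if (length(mzs) > 1 && diff(range(w)) > 1e-6)
      stop("continuous file has a non-uniform m/z array; supply 'axis' ",
           "and rebin")
    bw <- if (length(mzs) > 1) (mzs[length(mzs)] - mzs[1]) / (length(mzs) - 1)
      else if (!is.null(axis)) axis$bin_width
      else stop("single-bin file needs 'axis'")
    file_axis <- mass_axis(start = mzs[1] - bw / 2,
                           stop = mzs[1] - bw / 2 + length(mzs) * bw,
                           bin_width = bw)
    if (!is.null(axis)) {
      if (!axes_equal(axis, file_axis))
        stop("file mass axis does not match the requested axis")
      file_axis <- axis
    }
    trip <- list(i = integer(0), j = integer(0), x = numeric(0))
    ii <- jj <- list(); xx <- list()
    for (k in seq_along(recs)) {
      v <- read_array(recs[[k]]$intensity)
      nz <- which(v != 0)
      if (!length(nz)) next
      px <- pixel_index(nx, ys[k], xs[k])
      ii[[length(ii) + 1L]] <- rep.int(px, length(nz))
      jj[[length(jj) + 1L]] <- nz
      xx[[length(xx) + 1L]] <- v[nz]
    }
    counts <- Matrix::sparseMatrix(
      i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
      x = as.numeric(unlist(xx)),
      dims = c(nx * ny, file_axis$n_bins))
    if (length(spectra) < nx * ny)
      warning(nx * ny - length(spectra),
              " pixel(s) missing from file; left as zero spectra")
    spectral_image(counts, nx, ny, file_axis, polarity)
  } else {
    if (is.null(axis)) stop("processed-mode imzML requires an explicit 'axis'")
    ev <- list()
    for (k in seq_along(recs)) {
      mzv <- read_array(recs[[k]]$mz)
      v <- read_array(recs[[k]]$intensity)
      nz <- which(v != 0)
      if (!length(nz)) next
      ev[[length(ev) + 1L]] <- data.frame(
        pixel = pixel_index(nx, ys[k], xs[k]), mz = mzv[nz], intensity = v[nz])
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(pixel = integer(0), mz = numeric(0), intensity = numeric(0))
    if (length(spectra) < nx * ny)
      warning(nx * ny - length(spectra),
              " pixel(s) missing from file; left as zero spectra")
    bin_events(events, axis, nx, ny, polarity)
  }
}
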