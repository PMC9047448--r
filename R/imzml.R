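# Processed-mode imzML reader/writer.
#
# imzML stores an XML index (.imzML) next to a binary blob (.ibd) holding
# the per-pixel m/z and intensity arrays at byte offsets named in the XML.
# Only processed mode (per-pixel centroid lists) is supported; the whole
# pipeline is centroid-based. Coordinates follow the imzML convention of
# 1-based x (column) and y (row); they are mapped to this package's
# 0-based (row, col) as row = y - 1, col = x - 1.

ibd_path_for <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

write_imzml <- function(image, path) {
  if (!grepl("\\.imzml$", path, ignore.case = TRUE)) {
    stop("imzML output path must end in .imzML")
  }
  spectra <- image$spectra
  n <- length(spectra)
  uuid <- as.raw(rep(c(0x6d, 0x73, 0x69, 0x63), 4))  # fixed artifact UUID
  # .ibd first: uuid then, per spectrum, the mz and intensity doubles
  offsets <- matrix(0, nrow = max(n, 1), ncol = 2)
  lens <- integer(max(n, 1))
  ibd <- ibd_path_for(path)
  atomic_write(ibd, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeBin(uuid, con)
    pos <- 16
    for (i in seq_len(n)) {
      s <- spectra[[i]]
      lens[i] <<- length(s$mz)
      offsets[i, 1] <<- pos
      writeBin(as.double(s$mz), con, size = 8, endian = "little")
      pos <- pos + 8 * lens[i]
      offsets[i, 2] <<- pos
      writeBin(as.double(s$intensity), con, size = 8, endian = "little")
      pos <- pos + 8 * lens[i]
    }
  })
  uuid_str <- paste0(
    "{", paste0(format_uuid(uuid), collapse = ""), "}")
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    ' <cvList count="2">',
    '  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '  <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    ' </cvList>',
    ' <fileDescription>',
    '  <fileContent>',
    '   <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
    '   <cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>', uuid_str),
    '  </fileContent>',
    ' </fileDescription>',
    ' <referenceableParamGroupList count="2">',
    '  <referenceableParamGroup id="mzArray">',
    '   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '  </referenceableParamGroup>',
    '  <referenceableParamGroup id="intensityArray">',
    '   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
    '   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '  </referenceableParamGroup>',
    ' </referenceableParamGroupList>',
    ' <scanSettingsList count="1">',
    '  <scanSettings id="scanSettings1">',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', image$dims[2]),
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', image$dims[1]),
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%.10g"/>', image$pixel_um),
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%.10g"/>', image$pixel_um),
    '  </scanSettings>',
    ' </scanSettingsList>',
    ' <softwareList count="1">',
    '  <software id="msicelltyper" version="0.1.0"/>',
    ' </softwareList>',
    ' <instrumentConfigurationList count="1">',
    '  <instrumentConfiguration id="IC1"/>',
    ' </instrumentConfigurationList>',
    ' <dataProcessingList count="1">',
    '  <dataProcessing id="dp1">',
    '   <processingMethod order="1" softwareRef="msicelltyper">',
    '    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '   </processingMethod>',
    '  </dataProcessing>',
    ' </dataProcessingList>',
    ' <run id="run1" defaultInstrumentConfigurationRef="IC1">',
    sprintf('  <spectrumList count="%d" defaultDataProcessingRef="dp1">', n)
  )
  body <- character(0)
  if (n > 0) {
    body <- vapply(seq_len(n), function(i) {
      s <- spectra[[i]]
      paste0(
        sprintf('   <spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n', i, i - 1L, lens[i]),
        '    <scanList count="1">\n     <scan>\n',
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', s$coord[2] + 1L),
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', s$coord[1] + 1L),
        '     </scan>\n    </scanList>\n',
        '    <binaryDataArrayList count="2">\n',
        '     <binaryDataArray encodedLength="0">\n',
        '      <referenceableParamGroupRef ref="mzArray"/>\n',
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', lens[i]),
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * lens[i]),
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', offsets[i, 1]),
        '      <binary/>\n     </binaryDataArray>\n',
        '     <binaryDataArray encodedLength="0">\n',
        '      <referenceableParamGroupRef ref="intensityArray"/>\n',
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', lens[i]),
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', 8L * lens[i]),
        sprintf('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n', offsets[i, 2]),
        '      <binary/>\n     </binaryDataArray>\n',
        '    </binaryDataArrayList>\n   </spectrum>')
    }, character(1))
  }
  tail <- c('  </spectrumList>', ' </run>', '</mzML>')
  atomic_write(path, function(tmp) {
    writeLines(c(head, body, tail), tmp)
  })
  invisible(path)
}

format_uuid <- function(raw16) {
  hex <- format(raw16)
  paste0(paste0(hex[1:4], collapse = ""), "-", paste0(hex[5:6], collapse = ""),
         "-", paste0(hex[7:8], collapse = ""), "-",
         paste0(hex[9:10], collapse = ""), "-",
         paste0(hex[11:16], collapse = ""))
}

read_imzml <- function(path, pixel_um = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  fc <- xml2::xml_find_all(doc, "//fileDescription/fileContent/cvParam")
  acc <- xml2::xml_attr(fc, "accession")
  if ("IMS:1000030" %in% acc) {
    stop("continuous-mode imzML is not supported: centroid the data first")
  }
  if (!("IMS:1000031" %in% acc)) {
    stop("imzML file does not declare processed mode")
  }
  get_setting <- function(a) {
    node <- xml2::xml_find_first(
      doc, sprintf("//scanSettings/cvParam[@accession='%s']", a))
    if (inherits(node, "xml_missing")) NA_real_
    else as.numeric(xml2::xml_attr(node, "value"))
  }
  if (is.null(pixel_um)) {
    pixel_um <- get_setting("IMS:1000046")
    if (is.na(pixel_um)) pixel_um <- 1
  }
  max_x <- get_setting("IMS:1000042")
  max_y <- get_setting("IMS:1000043")
  specs <- xml2::xml_find_all(doc, "//run/spectrumList/spectrum")
  n <- length(specs)
  parse_spec <- function(node) {
    cv <- xml2::xml_find_all(node, ".//cvParam")
    a <- xml2::xml_attr(cv, "accession")
    v <- xml2::xml_attr(cv, "value")
    x <- as.integer(v[match("IMS:1000050", a)])
    y <- as.integer(v[match("IMS:1000051", a)])
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    out <- list(x = x, y = y, mz_off = NA_real_, int_off = NA_real_,
                len = NA_integer_)
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      acv <- xml2::xml_find_all(arr, "./cvParam")
      aa <- xml2::xml_attr(acv, "accession")
      av <- xml2::xml_attr(acv, "value")
      off <- as.numeric(av[match("IMS:1000102", aa)])
      len <- as.integer(av[match("IMS:1000103", aa)])
      is_mz <- identical(ref, "mzArray") || "MS:1000514" %in% aa
      if (is_mz) out$mz_off <- off else out$int_off <- off
      out$len <- len
    }
    out
  }
  infos <- lapply(specs, parse_spec)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) stop(sprintf("missing binary companion file %s", ibd))
  con <- file(ibd, "rb")
  on.exit(close(con))
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    info <- infos[[i]]
    if (anyNA(c(info$x, info$y, info$mz_off, info$int_off, info$len))) {
      stop(sprintf("malformed imzML spectrum entry %d in %s", i, path))
    }
    seek(con, where = info$mz_off)
    mz <- readBin(con, "double", n = info$len, size = 8, endian = "little")
    seek(con, where = info$int_off)
    it <- readBin(con, "double", n = info$len, size = 8, endian = "little")
    if (length(mz) < info$len || length(it) < info$len) {
      stop(sprintf("truncated .ibd file %s", ibd))
    }
    spectra[[i]] <- centroid_spectrum(mz, it,
                                      coord = c(info$y - 1L, info$x - 1L))
  }
  ys <- vapply(infos, function(z) z$y, integer(1))
  xs <- vapply(infos, function(z) z$x, integer(1))
  rows <- if (!is.na(max_y)) as.integer(max_y) else max(ys, 1L)
  cols <- if (!is.na(max_x)) as.integer(max_x) else max(xs, 1L)
  spectrum_image(spectra, dims = c(rows, cols), pixel_um = pixel_um,
                 metadata = list(source = path))
}
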