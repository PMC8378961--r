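// Minimal PNG codec backed by zlib: writes 8/16-bit grayscale, reads
// non-interlaced gray / gray+alpha / RGB / RGBA at bit depth 8 or 16
// (palette and sub-byte depths are rejected).  Values are exchanged with R
// as doubles in [0,1]; quantization happens here at the declared depth.

#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>
using namespace Rcpp;

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char* type,
                        const std::vector<unsigned char>& data) {
  std::vector<unsigned char> hdr;
  put_u32(hdr, (uint32_t)data.size());
  fwrite(hdr.data(), 1, 4, f);
  fwrite(type, 1, 4, f);
  if (!data.empty()) fwrite(data.data(), 1, data.size(), f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (!data.empty()) crc = crc32(crc, data.data(), (uInt)data.size());
  std::vector<unsigned char> tail;
  put_u32(tail, (uint32_t)crc);
  fwrite(tail.data(), 1, 4, f);
}

// [[Rcpp::export]]
void cpp_write_png_gray(std::string path, NumericMatrix img, int depth) {
  if (depth != 8 && depth != 16) stop("depth must be 8 or 16");
  int H = img.nrow(), W = img.ncol();
  double maxv = (depth == 8) ? 255.0 : 65535.0;
  int bps = depth / 8;
  size_t rowbytes = (size_t)W * bps;
  std::vector<unsigned char> raw((rowbytes + 1) * H);
  size_t pos = 0;
  for (int i = 0; i < H; ++i) {
    raw[pos++] = 0;  // filter: none
    for (int j = 0; j < W; ++j) {
      double v = img(i, j);
      if (v < 0) v = 0;
      if (v > 1) v = 1;
      uint32_t q = (uint32_t)std::floor(v * maxv + 0.5);
      if (depth == 8) {
        raw[pos++] = (unsigned char)q;
      } else {
        raw[pos++] = (unsigned char)(q >> 8);
        raw[pos++] = (unsigned char)(q & 0xff);
      }
    }
  }
  uLongf clen = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(clen);
  if (compress2(comp.data(), &clen, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("PNG compression failed");
  comp.resize(clen);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  static const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)W);
  put_u32(ihdr, (uint32_t)H);
  ihdr.push_back((unsigned char)depth);
  ihdr.push_back(0);  // color type: grayscale
  ihdr.push_back(0);  // compression
  ihdr.push_back(0);  // filter method
  ihdr.push_back(0);  // no interlace
  write_chunk(f, "IHDR", ihdr);
  write_chunk(f, "IDAT", comp);
  write_chunk(f, "IEND", std::vector<unsigned char>());
  std::fclose(f);
}

static int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
List cpp_read_png(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s' for reading", path.c_str());
  unsigned char sig[8];
  if (fread(sig, 1, 8, f) != 8 || sig[0] != 137 || sig[1] != 'P' ||
      sig[2] != 'N' || sig[3] != 'G') {
    std::fclose(f);
    stop("'%s' is not a PNG file", path.c_str());
  }
  uint32_t W = 0, H = 0;
  int depth = 0, colortype = 0, interlace = 0;
  std::vector<unsigned char> idat;
  bool done = false;
  while (!done) {
    unsigned char lenb[4], typeb[5] = {0};
    if (fread(lenb, 1, 4, f) != 4 || fread(typeb, 1, 4, f) != 4) {
      std::fclose(f);
      stop("truncated PNG '%s'", path.c_str());
    }
    uint32_t len = ((uint32_t)lenb[0] << 24) | ((uint32_t)lenb[1] << 16) |
                   ((uint32_t)lenb[2] << 8) | lenb[3];
    std::vector<unsigned char> data(len);
    if (len && fread(data.data(), 1, len, f) != len) {
      std::fclose(f);
      stop("truncated PNG chunk in '%s'", path.c_str());
    }
    fseek(f, 4, SEEK_CUR);  // skip CRC
    std::string type((char*)typeb);
    if (type == "IHDR") {
      W = ((uint32_t)data[0] << 24) | (data[1] << 16) | (data[2] << 8) | data[3];
      H = ((uint32_t)data[4] << 24) | (data[5] << 16) | (data[6] << 8) | data[7];
      depth = data[8];
      colortype = data[9];
      interlace = data[12];
    } else if (type == "IDAT") {
      idat.insert(idat.end(), data.begin(), data.end());
    } else if (type == "IEND") {
      done = true;
    }
  }
  std::fclose(f);
  if (interlace != 0) stop("interlaced PNG is not supported");
  if (depth != 8 && depth != 16)
    stop("PNG bit depth %d is not supported (need 8 or 16)", depth);
  int channels;
  switch (colortype) {
    case 0: channels = 1; break;
    case 2: channels = 3; break;
    case 4: channels = 2; break;
    case 6: channels = 4; break;
    default: stop("PNG color type %d (palette?) is not supported", colortype);
  }
  int bps = depth / 8;
  int bpp = bps * channels;  // bytes per pixel (for filtering)
  size_t rowbytes = (size_t)W * bpp;
  size_t rawlen = (rowbytes + 1) * H;
  std::vector<unsigned char> raw(rawlen);
  uLongf dlen = (uLongf)rawlen;
  if (uncompress(raw.data(), &dlen, idat.data(), (uLong)idat.size()) != Z_OK ||
      dlen != rawlen)
    stop("PNG inflate failed for '%s'", path.c_str());
  // undo scanline filters in place
  std::vector<unsigned char> prev(rowbytes, 0);
  for (uint32_t i = 0; i < H; ++i) {
    unsigned char* row = raw.data() + i * (rowbytes + 1);
    int ft = row[0];
    unsigned char* cur = row + 1;
    for (size_t t = 0; t < rowbytes; ++t) {
      int a = (t >= (size_t)bpp) ? cur[t - bpp] : 0;
      int b = prev[t];
      int c = (t >= (size_t)bpp) ? prev[t - bpp] : 0;
      int v = cur[t];
      switch (ft) {
        case 0: break;
        case 1: v = (v + a) & 0xff; break;
        case 2: v = (v + b) & 0xff; break;
        case 3: v = (v + (a + b) / 2) & 0xff; break;
        case 4: v = (v + paeth(a, b, c)) & 0xff; break;
        default: stop("bad PNG filter type %d", ft);
      }
      cur[t] = (unsigned char)v;
    }
    std::copy(cur, cur + rowbytes, prev.begin());
  }
  double maxv = (depth == 8) ? 255.0 : 65535.0;
  NumericVector out((R_xlen_t)H * W * channels);
  out.attr("dim") = IntegerVector::create(H, W, channels);
  double* op = REAL(out);
  for (uint32_t i = 0; i < H; ++i) {
    const unsigned char* cur = raw.data() + i * (rowbytes + 1) + 1;
    for (uint32_t j = 0; j < W; ++j)
      for (int c = 0; c < channels; ++c) {
        size_t t = ((size_t)j * channels + c) * bps;
        uint32_t q = (depth == 8) ? cur[t]
                                  : (((uint32_t)cur[t] << 8) | cur[t + 1]);
        op[i + (size_t)H * j + (size_t)H * W * c] = q / maxv;
      }
  }
  return List::create(_["pixels"] = out, _["depth"] = depth,
                      _["channels"] = channels);
}
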