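// PNG scanline unfiltering (filters 0-4 of the PNG spec) for the built-in
// codec.  `data` is the inflated IDAT stream: H rows of (1 filter byte +
// W*bpp sample bytes).  Returns the reconstructed samples, row-major.
#include <Rcpp.h>
using namespace Rcpp;

static inline int paeth(int a, int b, int c) {
  int p = a + b - c;
  int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
  if (pa <= pb && pa <= pc) return a;
  if (pb <= pc) return b;
  return c;
}

// [[Rcpp::export]]
RawVector cpp_png_unfilter(RawVector data, int height, int rowbytes, int bpp) {
  if ((R_xlen_t)(height) * (rowbytes + 1) != data.size())
    stop("corrupt PNG image data (unexpected length)");
  RawVector out((R_xlen_t)height * rowbytes);
  for (int r = 0; r < height; ++r) {
    const Rbyte *src = data.begin() + (R_xlen_t)r * (rowbytes + 1);
    Rbyte *cur = out.begin() + (R_xlen_t)r * rowbytes;
    const Rbyte *up = r > 0 ? cur - rowbytes : nullptr;
    int ft = src[0];
    const Rbyte *raw = src + 1;
    switch (ft) {
    case 0:
      for (int i = 0; i < rowbytes; ++i) cur[i] = raw[i];
      break;
    case 1:
      for (int i = 0; i < rowbytes; ++i)
        cur[i] = (Rbyte)(raw[i] + (i >= bpp ? cur[i - bpp] : 0));
      break;
    case 2:
      for (int i = 0; i < rowbytes; ++i)
        cur[i] = (Rbyte)(raw[i] + (up ? up[i] : 0));
      break;
    case 3:
      for (int i = 0; i < rowbytes; ++i) {
        int left = i >= bpp ? cur[i - bpp] : 0;
        int above = up ? up[i] : 0;
        cur[i] = (Rbyte)(raw[i] + ((left + above) >> 1));
      }
      break;
    case 4:
      for (int i = 0; i < rowbytes; ++i) {
        int left = i >= bpp ? cur[i - bpp] : 0;
        int above = up ? up[i] : 0;
        int ul = (up && i >= bpp) ? up[i - bpp] : 0;
        cur[i] = (Rbyte)(raw[i] + paeth(left, above, ul));
      }
      break;
    default:
      stop("unsupported PNG filter type %d", ft);
    }
  }
  return out;
}
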