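// Sequential bit-level codec kernels: GIF LZW compression and the H.264
// I_PCM slice writer. Both are inherently byte-serial, so they live in
// C++; all container/header logic stays in R.
#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct BitWriterLSB {  // GIF packs LZW codes least-significant-bit first
  std::vector<unsigned char> out;
  unsigned int acc = 0;
  int nbits = 0;
  void put(unsigned int code, int width) {
    acc |= code << nbits;
    nbits += width;
    while (nbits >= 8) {
      out.push_back(acc & 0xFF);
      acc >>= 8;
      nbits -= 8;
    }
  }
  void flush() {
    if (nbits > 0) out.push_back(acc & 0xFF);
    acc = 0; nbits = 0;
  }
};

struct BitWriterMSB {  // H.264 RBSP is most-significant-bit first
  std::vector<unsigned char> out;
  unsigned int acc = 0;
  int nbits = 0;
  void put(unsigned int v, int width) {
    for (int i = width - 1; i >= 0; --i) {
      acc = (acc << 1) | ((v >> i) & 1u);
      ++nbits;
      if (nbits == 8) { out.push_back(acc & 0xFF); acc = 0; nbits = 0; }
    }
  }
  void put_ue(unsigned int v) {
    unsigned int vp1 = v + 1;
    int nb = 0;
    for (unsigned int t = vp1; t > 0; t >>= 1) ++nb;
    put(0, nb - 1);
    put(vp1, nb);
  }
  void align_zero() { if (nbits > 0) put(0, 8 - nbits); }
  void put_bytes(const unsigned char* p, size_t n) {
    // only when byte aligned
    out.insert(out.end(), p, p + n);
  }
};

}  // namespace

// [[Rcpp::export(name = ".lzw_encode_gif")]]
RawVector lzw_encode_gif(IntegerVector indices, int min_code_size) {
  const int clear_code = 1 << min_code_size;
  const int eoi_code = clear_code + 1;
  // dictionary: next_entry[code][symbol]; 0 means absent, else code + 1
  const int nsym = 1 << min_code_size;
  std::vector<int> nxt((size_t)4096 * nsym, 0);
  BitWriterLSB bw;
  int code_size = min_code_size + 1;
  int next_code = eoi_code + 1;

  bw.put(clear_code, code_size);
  if (indices.size() == 0) {
    bw.put(eoi_code, code_size);
    bw.flush();
    return RawVector(bw.out.begin(), bw.out.end());
  }
  int cur = indices[0];
  for (R_xlen_t i = 1; i < indices.size(); ++i) {
    int c = indices[i];
    int& slot = nxt[(size_t)cur * nsym + c];
    if (slot != 0) {
      cur = slot - 1;
    } else {
      bw.put(cur, code_size);
      if (next_code < 4096) {
        slot = next_code + 1;
        if (next_code == (1 << code_size) && code_size < 12) ++code_size;
        ++next_code;
      } else {
        bw.put(clear_code, code_size);
        std::fill(nxt.begin(), nxt.end(), 0);
        code_size = min_code_size + 1;
        next_code = eoi_code + 1;
      }
      cur = c;
    }
  }
  bw.put(cur, code_size);
  bw.put(eoi_code, code_size);
  bw.flush();
  return RawVector(bw.out.begin(), bw.out.end());
}

// Emulation-prevention: insert 0x03 after any 00 00 followed by 00/01/02/03.
static std::vector<unsigned char> escape_rbsp(const std::vector<unsigned char>& rbsp) {
  std::vector<unsigned char> out;
  out.reserve(rbsp.size() + 16);
  int zeros = 0;
  for (unsigned char b : rbsp) {
    if (zeros >= 2 && b <= 0x03) {
      out.push_back(0x03);
      zeros = 0;
    }
    out.push_back(b);
    zeros = (b == 0x00) ? zeros + 1 : 0;
  }
  return out;
}

// [[Rcpp::export(name = ".escape_rbsp")]]
RawVector escape_rbsp_r(RawVector rbsp) {
  std::vector<unsigned char> in(rbsp.begin(), rbsp.end());
  std::vector<unsigned char> out = escape_rbsp(in);
  return RawVector(out.begin(), out.end());
}

// Build one complete IDR slice NAL (header byte + escaped RBSP) made of
// I_PCM macroblocks. Y is (16*mbH) x (16*mbW), Cb/Cr are (8*mbH) x (8*mbW),
// all integer matrices with samples in [1, 255] (PCM samples of 0 are not
// permitted by the standard). Matrices are row = y, col = x.
// [[Rcpp::export(name = ".h264_ipcm_slice")]]
RawVector h264_ipcm_slice(IntegerMatrix Y, IntegerMatrix Cb, IntegerMatrix Cr,
                          int idr_pic_id) {
  const int mbH = Y.nrow() / 16, mbW = Y.ncol() / 16;
  if (mbH * 16 != Y.nrow() || mbW * 16 != Y.ncol())
    stop("luma plane is not a multiple of 16");
  if (Cb.nrow() != Y.nrow() / 2 || Cb.ncol() != Y.ncol() / 2 ||
      Cr.nrow() != Cb.nrow() || Cr.ncol() != Cb.ncol())
    stop("chroma planes must be half the luma dimensions");

  BitWriterMSB bw;
  // slice header (IDR, pic_order_cnt_type = 2 in the SPS)
  bw.put_ue(0);        // first_mb_in_slice
  bw.put_ue(7);        // slice_type: I (all slices of picture)
  bw.put_ue(0);        // pic_parameter_set_id
  bw.put(0, 4);        // frame_num (log2_max_frame_num = 4)
  bw.put_ue((unsigned)idr_pic_id);  // idr_pic_id
  bw.put(0, 1);        // no_output_of_prior_pics_flag
  bw.put(0, 1);        // long_term_reference_flag
  bw.put(1, 1);        // slice_qp_delta = se(0) -> bit "1"

  std::vector<unsigned char> mb(384);
  for (int my = 0; my < mbH; ++my) {
    for (int mx = 0; mx < mbW; ++mx) {
      bw.put_ue(25);   // mb_type I_PCM
      bw.align_zero(); // pcm_alignment_zero_bit(s)
      size_t k = 0;
      for (int y = 0; y < 16; ++y)
        for (int x = 0; x < 16; ++x)
          mb[k++] = (unsigned char)Y(my * 16 + y, mx * 16 + x);
      for (int y = 0; y < 8; ++y)
        for (int x = 0; x < 8; ++x)
          mb[k++] = (unsigned char)Cb(my * 8 + y, mx * 8 + x);
      for (int y = 0; y < 8; ++y)
        for (int x = 0; x < 8; ++x)
          mb[k++] = (unsigned char)Cr(my * 8 + y, mx * 8 + x);
      bw.put_bytes(mb.data(), mb.size());
    }
  }
  bw.put(1, 1);        // rbsp_stop_one_bit
  bw.align_zero();

  std::vector<unsigned char> ebsp = escape_rbsp(bw.out);
  RawVector nal(ebsp.size() + 1);
  nal[0] = 0x65;       // nal_ref_idc = 3, nal_unit_type = 5 (IDR slice)
  std::memcpy(&nal[1], ebsp.data(), ebsp.size());
  return nal;
}
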