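PKG_LIBS = -lquadmath
PKG_CXXFLAGS = -fext-numeric-literals
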