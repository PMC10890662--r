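name,formula,lactone,hydroxyls,carboxyls,predicted_ri
GA7,C19H22O5,1,1,1,840.94
GA62,C19H22O5,1,1,1,685.27
GA88,C19H22O5,1,1,1,865.36
GA104,C19H22O5,1,1,1,716.94
GA105,C19H22O5,1,1,1,535.52
GA106,C19H22O5,1,1,1,796.48
GA107,C19H22O5,1,1,1,826.57
GA5,C19H22O5,0,0,1,
GA11,C19H22O5,0,0,1,
GA31,C19H22O5,0,1,1,
GA95,C19H22O5,0,1,1,
GA96,C19H22O5,0,1,1,
GA108,C19H22O5,0,0,1,
GA109,C19H22O5,0,0,1,
GA117,C19H22O5,0,1,1,
GA121,C19H22O5,0,0,1,
GA122,C19H22O5,0,1,1,
GA4,C19H24O5,1,1,1,
GA40,C19H24O5,1,1,1,
GA51,C19H24O5,1,1,1,
GA61,C19H24O5,1,1,1,
GA119,C19H24O5,1,1,1,
GA20,C19H24O5,0,0,1,
GA45,C19H24O5,0,1,1,
GA69,C19H24O5,0,1,1,
GA70,C19H24O5,0,1,1,
GA84,C19H24O5,0,0,1,
GA3,C19H22O6,1,1,1,653.94
GA6,C19H22O6,1,1,1,
GA30,C19H22O6,1,1,1,
GA68,C19H22O6,1,1,1,
GA80,C19H22O6,1,1,1,
GA92,C19H22O6,1,1,1,
GA22,C19H22O6,0,1,1,
GA94,C19H22O6,0,1,1,
GA126,C19H22O6,0,0,1,
GA16,C19H24O6,1,2,1,
GA34,C19H24O6,1,2,1,
GA47,C19H24O6,1,2,1,
GA54,C19H24O6,1,2,1,
GA90,C19H24O6,1,2,1,
GA1,C19H24O6,1,1,1,
GA29,C19H24O6,1,1,1,
GA35,C19H24O6,1,1,1,
GA58,C19H24O6,0,1,1,
GA60,C19H24O6,0,1,1,
GA63,C19H24O6,0,1,1,
GA67,C19H24O6,0,1,1,
GA71,C19H24O6,0,1,1,
GA77,C19H24O6,0,0,1,
GA81,C19H24O6,0,1,1,
GA118,C19H24O6,0,1,1,
GA130,C19H24O6,0,0,1,
GA131,C19H24O6,0,1,1,
GA136,C19H24O6,0,0,1,
GA2,C19H26O6,1,1,1,
GA82,C19H26O6,1,1,1,
GA52,C20H26O7,1,2,2,
GA13,C20H26O7,1,1,3,
GA17,C20H26O7,0,1,3,
GA23,C20H26O7,1,1,2,
GA46,C20H26O7,0,1,2,
GA66,C20H26O7,0,1,2,
GA99,C20H26O7,0,0,2,
GA102,C20H26O7,0,1,2,
GA125,C20H26O7,0,0,2,
GA129,C20H26O7,0,1,2,
GA8,C19H24O7,1,2,1,
GA9,C19H24O4,1,0,1,
GA12,C20H28O4,0,0,2,
GA15,C20H26O5,0,0,1,
GA19,C20H26O6,0,0,2,
GA24,C20H28O5,0,0,2,
GA44,C20H26O6,0,0,1,
GA53,C20H28O6,0,1,2,
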