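label	x	y	z
Fz	-0.004165	0.857248	0.514886
Cz	-0.003492	0.096157	0.995360
Pz	-0.003975	-0.723370	0.690449
Oz	-0.005803	-0.997747	-0.066831
PO7	-0.556883	-0.809745	-0.184918
PO8	0.552697	-0.812379	-0.185919
O1	-0.297839	-0.946708	-0.122617
O2	0.290231	-0.948932	-0.123671
C3	-0.835450	0.065391	0.545663
C4	0.840889	0.074674	0.536032
T7	-0.940742	0.008668	-0.339014
T8	0.939517	0.019815	-0.341930
P3	-0.602882	-0.696113	0.389820
P4	0.611495	-0.686793	0.392924
F3	-0.572185	0.785564	0.235570
F4	0.569947	0.792176	0.218213
Fpz	-0.005262	0.976962	-0.213350
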