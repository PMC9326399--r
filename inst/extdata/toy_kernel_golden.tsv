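sample_id	S001	S002	S003	S004	S005	S006	S007	S008	S009	S010	S011	S012
S001	1	0.716531310573789	0.725360566218624	0.783058236508146	0.026126959256035	0.00761278727646848	0.00823437346818073	0.0162575417450451	0.0187632547604326	0.0142431054425535	0.0165351080412684	0.0320246886605968
S002	0.716531310573789	1	0.744159839714322	0.721917899002142	0.0145001682619808	0.00457332458111109	0.00506393592019905	0.0143535488156345	0.00677690237550299	0.00843719257122075	0.00819315914297114	0.0167471491953333
S003	0.725360566218624	0.744159839714322	1	0.750373814673949	0.0187398315305882	0.00429480291293346	0.0073621481301039	0.0291043313140715	0.0143416596203064	0.0174726139507601	0.0127203484457972	0.0321618214545271
S004	0.783058236508146	0.721917899002142	0.750373814673949	1	0.00822042616338338	0.00166777613347627	0.0023967788372698	0.00768184079024098	0.00705010578428966	0.00427310133643463	0.00420369005776274	0.013933960298233
S005	0.026126959256035	0.0145001682619808	0.0187398315305882	0.00822042616338338	1	0.549208259002263	0.599101927926458	0.614195671089281	0.585696232036833	0.561921127419018	0.557585306754227	0.677916106334639
S006	0.00761278727646848	0.00457332458111109	0.00429480291293346	0.00166777613347627	0.549208259002263	1	0.623417128217552	0.658695753845747	0.651952106012506	0.717289624489499	0.773058434774633	0.489881077313043
S007	0.00823437346818073	0.00506393592019905	0.0073621481301039	0.0023967788372698	0.599101927926458	0.623417128217552	1	0.599241508463389	0.703718850016064	0.718838062825051	0.728331406691658	0.613000363248559
S008	0.0162575417450451	0.0143535488156345	0.0291043313140715	0.00768184079024098	0.614195671089281	0.658695753845747	0.599241508463389	1	0.703005628722347	0.606355054233906	0.643996049023852	0.587846125243136
S009	0.0187632547604326	0.00677690237550299	0.0143416596203064	0.00705010578428966	0.585696232036833	0.651952106012506	0.703718850016064	0.703005628722347	1	0.605339736578381	0.684522236819785	0.660253345739891
S010	0.0142431054425535	0.00843719257122075	0.0174726139507601	0.00427310133643463	0.561921127419018	0.717289624489499	0.718838062825051	0.606355054233906	0.605339736578381	1	0.716531310573789	0.405501657529469
S011	0.0165351080412684	0.00819315914297114	0.0127203484457972	0.00420369005776274	0.557585306754227	0.773058434774633	0.728331406691658	0.643996049023852	0.684522236819785	0.716531310573789	1	0.522097679216324
S012	0.0320246886605968	0.0167471491953333	0.0321618214545271	0.013933960298233	0.677916106334639	0.489881077313043	0.613000363248559	0.587846125243136	0.660253345739891	0.405501657529469	0.522097679216324	1
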