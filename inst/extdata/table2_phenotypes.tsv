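patient_id	field	value
A01203	sex	M
A02903	sex	F
A05503	sex	M
A06603	sex	M
A08203	sex	M
A01203	father_variant	-
A02903	father_variant	-
A05503	father_variant	-
A06603	father_variant	-
A08203	father_variant	-
A01203	mother_variant	-
A02903	mother_variant	+
A05503	mother_variant	-
A06603	mother_variant	-
A08203	mother_variant	-
A01203	age_of_onset_months	30
A02903	age_of_onset_months	5
A05503	age_of_onset_months	7
A06603	age_of_onset_months	5
A08203	age_of_onset_months	3
A01203	onset_abnormal_eye_movement	-
A02903	onset_abnormal_eye_movement	-
A05503	onset_abnormal_eye_movement	-
A06603	onset_abnormal_eye_movement	+
A08203	onset_abnormal_eye_movement	-
A01203	onset_dystonia	-
A02903	onset_dystonia	+
A05503	onset_dystonia	+
A06603	onset_dystonia	-
A08203	onset_dystonia	+
A01203	onset_hemiplegia	+
A02903	onset_hemiplegia	-
A05503	onset_hemiplegia	+
A06603	onset_hemiplegia	-
A08203	onset_hemiplegia	-
A01203	onset_quadriplegia	-
A02903	onset_quadriplegia	-
A05503	onset_quadriplegia	-
A06603	onset_quadriplegia	-
A08203	onset_quadriplegia	-
A01203	onset_seizure	-
A02903	onset_seizure	-
A05503	onset_seizure	-
A06603	onset_seizure	-
A08203	onset_seizure	-
A01203	hemiplegia_start_months	30
A02903	hemiplegia_start_months	11
A05503	hemiplegia_start_months	7
A06603	hemiplegia_start_months	8
A08203	hemiplegia_start_months	3
A01203	hemiplegia_duration_days	0.01~4
A02903	hemiplegia_duration_days	2~7
A05503	hemiplegia_duration_days	0.01~3
A06603	hemiplegia_duration_days	1~2
A08203	hemiplegia_duration_days	2~3
A01203	hemiplegia_frequency_per_month	3~15
A02903	hemiplegia_frequency_per_month	1~2
A05503	hemiplegia_frequency_per_month	2~3
A06603	hemiplegia_frequency_per_month	2
A08203	hemiplegia_frequency_per_month	2~3
A01203	course_quadriplegia	Uncertain
A02903	course_quadriplegia	+
A05503	course_quadriplegia	+
A06603	course_quadriplegia	-
A08203	course_quadriplegia	-
A01203	course_abnormal_eye_movement	+
A02903	course_abnormal_eye_movement	+
A05503	course_abnormal_eye_movement	-
A06603	course_abnormal_eye_movement	+
A08203	course_abnormal_eye_movement	-
A01203	course_dystonia	+
A02903	course_dystonia	+
A05503	course_dystonia	+
A06603	course_dystonia	+
A08203	course_dystonia	+
A01203	epilepsy	-
A02903	epilepsy	-
A05503	epilepsy	-
A06603	epilepsy	-
A08203	epilepsy	-
A01203	autonomic_dysfunction	-
A02903	autonomic_dysfunction	-
A05503	autonomic_dysfunction	-
A06603	autonomic_dysfunction	-
A08203	autonomic_dysfunction	-
A01203	dysphagia	+
A02903	dysphagia	-
A05503	dysphagia	-
A06603	dysphagia	-
A08203	dysphagia	-
A01203	dysarthria	+
A02903	dysarthria	-
A05503	dysarthria	-
A06603	dysarthria	-
A08203	dysarthria	-
A01203	respiratory_disturbance	-
A02903	respiratory_disturbance	-
A05503	respiratory_disturbance	-
A06603	respiratory_disturbance	-
A08203	respiratory_disturbance	-
A01203	ataxia	-
A02903	ataxia	Uncertain
A05503	ataxia	+
A06603	ataxia	+
A08203	ataxia	-
A01203	developmental_delay	+
A02903	developmental_delay	+
A05503	developmental_delay	+
A06603	developmental_delay	+
A08203	developmental_delay	Uncertain
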